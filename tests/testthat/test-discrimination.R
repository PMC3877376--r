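test_that("AUC matches exhaustive pairwise comparison", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1)),
               pairwise_auc(c(1, 2, 2, 3), c(0, 1, 0, 1)))
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  # random tied data, n <= 200, against the brute-force oracle
  set.seed(51)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    s <- sample(1:8, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), pairwise_auc(s, y))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC of an uninformative score is near one half", {
  set.seed(52)
  y <- rbinom(4000, 1, 0.5)
  expect_equal(roc_auc(rnorm(4000), y), 0.5, tolerance = 0.03)
})

test_that("AUC is invariant under strictly increasing transformations", {
  set.seed(53)
  s <- rnorm(300); y <- rbinom(300, 1, plogis(s))
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
  expect_equal(roc_auc(s, y), roc_auc(qlogis(plogis(s)), y),
               tolerance = 1e-12)
})

test_that("AUC and its DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(54)
  s <- rnorm(250); y <- rbinom(250, 1, plogis(0.8 * s))
  mine <- roc_auc(s, y, ci = TRUE)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci95[1], ref_ci[1], tolerance = 1e-6)
  expect_equal(mine$ci95[2], ref_ci[3], tolerance = 1e-6)
})

test_that("paired DeLong contrast agrees with pROC and handles identity", {
  set.seed(55)
  y <- rbinom(300, 1, 0.45)
  a <- rnorm(300) + 0.7 * y
  b <- rnorm(300) + 0.4 * y
  ct <- auc_contrast(a, b, y)
  expect_equal(ct$delta, roc_auc(a, y) - roc_auc(b, y))
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-8)
  same <- auc_contrast(a, a, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_error(auc_contrast(a, b[-1], y), "paired")
})

test_that("DeLong p-value is consistent with a paired bootstrap oracle", {
  set.seed(56)
  n <- 150
  y <- rep(c(0, 1), c(90, 60))
  signal <- rnorm(n)
  a <- signal + 0.9 * y + rnorm(n, sd = 0.8)
  b <- signal + 0.55 * y + rnorm(n, sd = 0.8)
  ct <- auc_contrast(a, b, y)
  B <- 10000
  cases <- which(y == 1); ctrls <- which(y == 0)
  boot <- numeric(B)
  for (i in seq_len(B)) {
    idx <- c(sample(cases, replace = TRUE), sample(ctrls, replace = TRUE))
    boot[i] <- roc_auc(a[idx], y[idx]) - roc_auc(b[idx], y[idx])
  }
  z_boot <- ct$delta / sd(boot)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_equal(ct$se, sd(boot), tolerance = 0.15 * sd(boot))
  expect_equal(ct$p, p_boot, tolerance = 0.05)
})

test_that("the five-model suite is paired, ordered and monotone", {
  p <- default_panel()
  co <- simulate_case_control(
    cohort_config(700, 500, p, pigmentation_r2 = 0.03, seed = 57))
  pr <- compute_prs(co, p)
  suite <- build_model_suite(co, pr)
  expect_equal(suite$summary$model,
               c("single_snp", "prs_only", "sex_age", "sex_age_pigment",
                 "sex_age_pigment_prs"))
  expect_true(all(suite$probs >= 0 & suite$probs <= 1))
  expect_true(all(suite$summary$n == suite$n_used)) # identical subset
  auc <- setNames(suite$summary$auc, suite$summary$model)
  # nested in-sample fits cannot lose AUC by adding the PRS
  expect_gte(auc["sex_age_pigment_prs"], auc["sex_age_pigment"])
  expect_gt(auc["prs_only"], auc["single_snp"])
  # AUC is invariant to the monotone logistic link: scoring by the PRS
  # itself equals scoring by model 2's fitted probabilities
  expect_equal(unname(auc["prs_only"]),
               roc_auc(pr$weighted_score[suite$kept], suite$labels),
               tolerance = 1e-12)
})

test_that("suites without pigmentation data fail with a clear message", {
  p <- default_panel()
  co <- simulate_case_control(
    cohort_config(100, 100, p, covariate_scheme = "nhs", seed = 58))
  pr <- compute_prs(co, p)
  expect_error(build_model_suite(co, pr), "pigmentation covariates")
})

test_that("ROC coordinates integrate back to the Mann-Whitney AUC", {
  set.seed(59)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  rc <- roc_coordinates(s, y)
  expect_true(all(diff(rc$sensitivity) >= 0))
  # trapezoidal area under sens vs 1-spec
  fpr <- 1 - rc$specificity
  area <- sum(diff(fpr) * (head(rc$sensitivity, -1) +
                             tail(rc$sensitivity, -1)) / 2)
  expect_equal(area, roc_auc(s, y), tolerance = 1e-10)
})
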
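test_that("logistic MLE equals the closed-form 2x2 odds ratio", {
  d <- expand_2x2(30, 10, 20, 40)
  est <- fit_logistic(d$y, data.frame(exposed = d$x))
  expect_equal(est$or_point, 6.0, tolerance = 1e-8)
  # Woolf SE of log OR for the 2x2 table
  expect_equal(est$se, sqrt(1/30 + 1/10 + 1/20 + 1/40), tolerance = 1e-6)
  expect_equal(est$ci_low, exp(est$log_or - 1.959964 * est$se))
  expect_equal(est$ci_high, exp(est$log_or + 1.959964 * est$se))
})

test_that("dosage-coded fit matches a grid-search likelihood maximiser", {
  set.seed(31)
  x <- rbinom(300, 2, 0.3)
  y <- rbinom(300, 1, plogis(-0.5 + 0.4 * x))
  est <- fit_logistic(y, data.frame(dosage = x))
  oracle <- grid_logistic(y, x)
  expect_equal(est$log_or, unname(oracle["b1"]), tolerance = 1e-4)
})

test_that("null predictors give OR near 1 with covering CIs", {
  set.seed(32)
  y <- rep(c(0, 1), each = 100)
  x <- rnorm(200)
  est <- fit_logistic(y, data.frame(x = x))
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)
})

test_that("degenerate fits fail loudly", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rep(0, 20), rep(1, 20)) # complete separation
  expect_error(fit_logistic(y, data.frame(x = x)), "separation")
  expect_error(fit_logistic(rep(1, 30), data.frame(x = rnorm(30))),
               "event")
})

test_that("single-SNP association is oriented and symmetric under flips", {
  p <- one_snp_panel()
  co <- simulate_case_control(
    cohort_config(500, 500, p, per_snp_log_or = log(1.43), seed = 41))
  est <- single_snp_association(co, "rs12913832")
  flipped <- co
  flipped$rs12913832 <- 2L - co$rs12913832
  est_f <- single_snp_association(flipped, "rs12913832")
  expect_equal(est_f$or_point, 1 / est$or_point, tolerance = 1e-8)
  expect_equal(est_f$p, est$p, tolerance = 1e-8)
  mono <- co; mono$rs12913832 <- 1L
  expect_error(single_snp_association(mono, "rs12913832"), "monomorphic")
  expect_error(single_snp_association(co, "rs999"), "no dosage column")
})

test_that("estimates are invariant to row order and covariate recoding", {
  p <- default_panel()
  co <- simulate_case_control(cohort_config(400, 400, p, seed = 43))
  pr <- compute_prs(co, p)
  a <- prs_association(co, pr, "continuous", adjust = TRUE)
  perm <- sample(nrow(co))
  b <- prs_association(co[perm, ], pr[perm, ], "continuous", adjust = TRUE)
  expect_equal(a$log_or, b$log_or, tolerance = 1e-8)
  # affine recoding of age leaves the PRS coefficient unchanged
  co2 <- co; co2$age <- (co$age - 50) / 10
  c_ <- prs_association(co2, pr, "continuous", adjust = TRUE)
  expect_equal(a$log_or, c_$log_or, tolerance = 1e-6)
})

test_that("tertile, band and top-percentile contrasts report the right cell", {
  p <- default_panel()
  co <- simulate_case_control(cohort_config(600, 600, p, seed = 44))
  pr <- compute_prs(co, p)
  t31 <- prs_association(co, pr, "tertile31")
  # oracle: collapsed 2x2 of T3 vs T1 (T2 dropped) equals the indicator fit
  keep <- pr$tertile != "T2"
  tab <- table(pr$tertile[keep], co$case[keep])
  or_2x2 <- (tab["T3", "1"] * tab["T1", "0"]) /
    (tab["T1", "1"] * tab["T3", "0"])
  expect_equal(t31$or_point, or_2x2, tolerance = 1e-6)
  top <- prs_association(co, pr, "top5pct")
  tab2 <- table(pr$top5pct, co$case)
  expect_equal(top$or_point,
               (tab2["1", "1"] * tab2["0", "0"]) /
                 (tab2["0", "1"] * tab2["1", "0"]),
               tolerance = 1e-6)
})

test_that("band contrast matches the collapsed 2x2 table on enriched data", {
  p <- snp_panel(paste0("rs", 1:11), rep("A", 11), rep(0.15, 11),
                 rep(0.5, 11))
  set.seed(45)
  # mixture of low- and high-frequency strata so every band is populated
  d <- rbind(matrix(rbinom(600 * 11, 2, 0.25), 600, 11,
                    dimnames = list(NULL, p$snp_id)),
             matrix(rbinom(500 * 11, 2, 0.70), 500, 11,
                    dimnames = list(NULL, p$snp_id)))
  counts <- count_risk_alleles(d, p)
  y <- rbinom(nrow(d), 1, plogis(-0.5 + 0.15 * (counts - mean(counts))))
  co <- data.frame(study = "mdacc", case = y, d, check.names = FALSE)
  pr <- compute_prs(d, p)
  est <- prs_association(co, pr, "band")
  keep <- pr$allele_band != "7-14"
  tab <- table(pr$allele_band[keep], y[keep])
  or_2x2 <- (tab[">=15", "1"] * tab["<=6", "0"]) /
    (tab["<=6", "1"] * tab[">=15", "0"])
  expect_equal(est$or_point, or_2x2, tolerance = 1e-6)
})

test_that("requesting unavailable covariates names the scheme", {
  p <- tiny_panel()
  co <- simulate_case_control(
    cohort_config(80, 80, p, covariate_scheme = "hpfs", seed = 46))
  co$family_history <- NA_integer_
  pr <- compute_prs(co, p)
  expect_error(prs_association(co, pr, "continuous", adjust = TRUE),
               "family_history.*hpfs")
})

test_that("variance explained follows the squared-correlation convention", {
  set.seed(47)
  s <- rnorm(500)
  expect_equal(variance_explained(s, 3 + 2 * s), 1.0)
  expect_lt(variance_explained(s, rnorm(500)), 0.02)
  expect_error(variance_explained(s, rep(2, 500)), "constant")
})
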
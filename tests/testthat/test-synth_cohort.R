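test_that("panel construction enforces its invariants", {
  expect_error(snp_panel("rs1", "A", 0.1, 0), "strictly inside")
  expect_error(snp_panel("rs1", "A", 0.1, 1), "strictly inside")
  expect_error(snp_panel(c("rs1", "rs1"), c("A", "G"), c(0.1, 0.2),
                         c(0.3, 0.4)), "unique")
  expect_error(snp_panel("rs1", "A", Inf, 0.3), "finite")
  expect_error(snp_panel("rs1", "X", 0.1, 0.3), "nucleotide")
  p <- default_panel()
  expect_equal(nrow(p), 11)
  expect_true(all(p$risk_allele_freq > 0 & p$risk_allele_freq < 1))
})

test_that("genotypes follow Hardy-Weinberg proportions within Monte Carlo error", {
  p <- snp_panel("rs7412746", "T", 0.14, 0.4452)
  n <- 50000
  g <- simulate_genotypes(p, n, seed = 11)
  f <- 0.4452
  hwe <- c(`0` = (1 - f)^2, `1` = 2 * f * (1 - f), `2` = f^2)
  obs <- tabulate(g + 1L, 3) / n
  mc_se <- sqrt(hwe * (1 - hwe) / n)
  expect_true(all(abs(obs - hwe) < 3 * mc_se))
  # mean dosage = 2f
  expect_equal(mean(g), 2 * f, tolerance = 3 * sqrt(2 * f * (1 - f) / n))
})

test_that("genotype simulation handles boundary frequencies", {
  p_hi <- snp_panel("rs_hi", "A", 0, 1 - 1e-6)
  g <- simulate_genotypes(p_hi, 20000, seed = 3)
  expect_equal(mean(g), 2, tolerance = 1e-3)
  expect_error(snp_panel("rs0", "A", 0, 0))
})

test_that("same seed gives a bit-identical cohort", {
  cfg <- cohort_config(60, 80, tiny_panel(), covariate_scheme = "nhs",
                       seed = 99)
  expect_identical(simulate_case_control(cfg), simulate_case_control(cfg))
})

test_that("case-control sampling hits exact quotas and respects schemes", {
  p <- tiny_panel()
  for (sc in c("mdacc", "nhs", "hpfs")) {
    co <- simulate_case_control(
      cohort_config(70, 90, p, covariate_scheme = sc, seed = 5))
    expect_equal(sum(co$case == 1), 70)
    expect_equal(sum(co$case == 0), 90)
    g <- dosage_matrix(co, p)
    expect_true(all(g %in% 0:2))
  }
  nhs <- simulate_case_control(
    cohort_config(40, 60, p, covariate_scheme = "nhs", seed = 6))
  expect_true(all(nhs$sex == "female"))
  expect_true(all(is.na(nhs$skin_color)))
  expect_false(anyNA(nhs$family_history))
  hpfs <- simulate_case_control(
    cohort_config(40, 60, p, covariate_scheme = "hpfs", seed = 6))
  expect_true(all(hpfs$sex == "male"))
  expect_false(anyNA(hpfs$eye_color))
  expect_true(all(is.na(hpfs$tanning_ability)))
})

test_that("unattainable case quotas fail explicitly", {
  cfg <- cohort_config(500, 5, tiny_panel(), baseline_log_odds = -30,
                       seed = 1)
  expect_error(simulate_case_control(cfg, max_attempts = 3),
               "could not accrue")
})

test_that("pigmentation calibration tracks the requested r-squared", {
  p <- default_panel()
  co0 <- simulate_case_control(
    cohort_config(700, 700, p, pigmentation_r2 = 0, seed = 21))
  pr0 <- compute_prs(co0, p)
  expect_lt(variance_explained(pr0$weighted_score, co0$skin_color), 0.01)
  co3 <- simulate_case_control(
    cohort_config(1500, 1500, p, pigmentation_r2 = 0.03, seed = 22))
  pr3 <- compute_prs(co3, p)
  r2 <- variance_explained(pr3$weighted_score, co3$skin_color)
  # categorizing the latent trait attenuates the correlation somewhat
  expect_gt(r2, 0.01)
  expect_lt(r2, 0.05)
  expect_error(cohort_config(10, 10, p, pigmentation_r2 = 0.2),
               "pigmentation_r2")
})

test_that("null effects give calibrated type-I error for the per-SNP Wald test", {
  p <- one_snp_panel(freq = 0.3, weight = 0)
  set.seed(4242)
  reps <- 300
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    cfg <- cohort_config(120, 120, p, per_snp_log_or = 0,
                         baseline_log_odds = -1,
                         seed = sample.int(1e8, 1))
    co <- simulate_case_control(cfg)
    est <- single_snp_association(co, "rs12913832")
    rej[i] <- est$p < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("the three-study ensemble matches the published structure", {
  studies <- simulate_three_studies(master_seed = 17)
  expect_named(studies, c("mdacc", "nhs", "hpfs"))
  expect_equal(sum(studies$mdacc$case == 1), 1804)
  expect_equal(sum(studies$mdacc$case == 0), 1025)
  expect_equal(sum(studies$nhs$case == 1), 317)
  expect_equal(sum(studies$nhs$case == 0), 3376)
  expect_equal(sum(studies$hpfs$case == 1), 177)
  expect_equal(sum(studies$hpfs$case == 0), 2251)
  expect_true(all(studies$nhs$sex == "female"))
  expect_true(all(studies$hpfs$sex == "male"))
  expect_false(anyNA(studies$hpfs$eye_color))
  expect_true(all(is.na(studies$hpfs$tanning_ability)))
  expect_true(all(is.na(studies$mdacc$family_history)))
})
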
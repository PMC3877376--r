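# Study-specific covariate schemes. Availability and category marginals
# follow the published control distributions of the three cohorts:
# MDACC (case-control, both sexes, full pigmentation, no family history),
# NHS (all female; hair, tanning, family history), HPFS (all male; hair,
# eye, family history).
SCHEMES <- c("mdacc", "nhs", "hpfs")

scheme_covariates <- function(scheme) {
  switch(match.arg(scheme, SCHEMES),
    mdacc = c("sex", "age", "skin_color", "eye_color", "hair_color",
              "tanning_ability"),
    nhs = c("age", "hair_color", "tanning_ability", "family_history"),
    hpfs = c("age", "hair_color", "eye_color", "family_history"))
}

# latent-trait category layouts, ordered from low latent (dark/robust
# pigmentation) to high latent (fair/sun-sensitive); proportions are the
# published control marginals of the scheme's study
scheme_traits <- function(scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  skin <- list(levels = c("dark", "medium", "light"),
               props = c(0.077, 0.478, 0.445))
  eye_mdacc <- list(levels = c("brown/black", "hazel/green", "blue/gray"),
                    props = c(0.305, 0.354, 0.341))
  eye_hpfs <- list(levels = c("brown/black", "hazel/green", "blue/gray"),
                   props = c(0.324, 0.318, 0.358))
  hair <- function(black, brown, red, blonde)
    list(levels = c("black", "brown", "red", "blonde"),
         props = c(black, brown, red, blonde))
  tan <- function(deep, average, light, none)
    list(levels = c("deep tan", "average tan", "light tan", "practically none"),
         props = c(deep, average, light, none))
  switch(scheme,
    mdacc = list(skin_color = skin, eye_color = eye_mdacc,
                 hair_color = hair(0.056, 0.718, 0.037, 0.189),
                 tanning_ability = tan(0.266, 0.314, 0.303, 0.117)),
    nhs = list(hair_color = hair(0.026, 0.826, 0.034, 0.114),
               tanning_ability = tan(0.251, 0.463, 0.213, 0.074)),
    hpfs = list(hair_color = hair(0.094, 0.763, 0.026, 0.116),
                eye_color = eye_hpfs))
}

scheme_demographics <- function(scheme) {
  switch(match.arg(scheme, SCHEMES),
    mdacc = list(p_male = 0.59, age_mean = 52, age_sd = 13.5,
                 fh_case = NA, fh_control = NA),
    nhs = list(p_male = 0, age_mean = 57, age_sd = 6.7,
               fh_case = 0.199, fh_control = 0.079),
    hpfs = list(p_male = 1, age_mean = 61, age_sd = 8.5,
                fh_case = 0.124, fh_control = 0.049))
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP's dosage is the sum of two independent Bernoulli draws at the
#' panel's risk-allele frequency, so genotype proportions converge to the
#' HWE expectations (q^2, 2pq, p^2 for dosages 0/1/2 with risk-allele
#' frequency p). SNPs are mutually independent (the panel is assumed free
#' of linkage disequilibrium).
#'
#' @param panel a [snp_panel].
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed; when given, the RNG state is set
#'   before sampling.
#' @return An integer matrix, `n` rows by `nrow(panel)` columns, with
#'   dosages in \{0, 1, 2\} and column names `panel$snp_id`.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(panel$risk_allele_freq,
              function(p) stats::rbinom(n, 2L, p), integer(n))
  g <- matrix(as.integer(g), nrow = n,
              dimnames = list(NULL, panel$snp_id))
  g
}

#' Cohort simulation configuration
#'
#' @param n_cases,n_controls target counts (>= 1).
#' @param panel a [snp_panel].
#' @param per_snp_log_or per-SNP log odds ratio per risk allele used in
#'   the disease model; defaults to the panel weights.
#' @param baseline_log_odds intercept of the logistic disease model.
#' @param covariate_scheme one of `"mdacc"`, `"nhs"`, `"hpfs"`.
#' @param pigmentation_r2 target squared correlation between the weighted
#'   PRS and each latent pigmentation trait, in \[0, 0.05\].
#' @param seed integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases, n_controls, panel = default_panel(),
                          per_snp_log_or = panel$weight,
                          baseline_log_odds = -1.2,
                          covariate_scheme = "mdacc",
                          pigmentation_r2 = 0.03,
                          seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, inherits(panel, "snp_panel"),
            length(per_snp_log_or) == nrow(panel),
            all(is.finite(per_snp_log_or)), is.finite(baseline_log_odds))
  if (pigmentation_r2 < 0 || pigmentation_r2 > 0.05)
    stop("pigmentation_r2 must lie in [0, 0.05]")
  covariate_scheme <- match.arg(covariate_scheme, SCHEMES)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 panel = panel, per_snp_log_or = per_snp_log_or,
                 baseline_log_odds = baseline_log_odds,
                 covariate_scheme = covariate_scheme,
                 pigmentation_r2 = pigmentation_r2,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

cut_latent <- function(latent, spec) {
  cuts <- stats::qnorm(cumsum(spec$props[-length(spec$props)]) / sum(spec$props))
  idx <- findInterval(latent, cuts) + 1L
  factor(spec$levels[idx], levels = spec$levels)
}

#' Simulate a case-control cohort
#'
#' Disease status follows an additive logistic model on the risk-allele
#' dosages: `P(case) = plogis(baseline_log_odds + sum_j beta_j * g_j)`.
#' Individuals are drawn from the population model and assigned
#' case/control by Bernoulli sampling until exactly `n_cases` and
#' `n_controls` accrue (rejection sampling; odds ratios are invariant to
#' this outcome-dependent sampling). Pigmentation traits are generated
#' from a latent Gaussian `sqrt(r2) * z_PRS + sqrt(1 - r2) * eps` so the
#' squared correlation with the weighted PRS equals `pigmentation_r2`,
#' then cut at fixed normal quantiles matching the study's published
#' control marginals. Covariates not collected under the scheme are `NA`.
#'
#' @param config a [cohort_config].
#' @param max_attempts maximum number of sampling blocks before giving up
#'   (guards against unattainable case counts under extreme baselines).
#' @return A `data.frame` of class `cohort_table`: columns `study`, `id`,
#'   `case`, `sex`, `age`, `skin_color`, `eye_color`, `hair_color`,
#'   `tanning_ability`, `family_history`, then one integer dosage column
#'   per panel SNP.
#' @export
simulate_case_control <- function(config, max_attempts = 1000L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panel <- config$panel
  need_cases <- config$n_cases
  need_controls <- config$n_controls
  block <- max(2000L, need_cases + need_controls)
  got_cases <- got_controls <- vector("list", 0L)
  n_cases <- n_controls <- 0L
  attempts <- 0L
  while ((n_cases < need_cases || n_controls < need_controls)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not accrue ", need_cases, " cases / ", need_controls,
           " controls after ", max_attempts,
           " sampling blocks; baseline_log_odds may be too extreme")
    g <- simulate_genotypes(panel, block)
    eta <- config$baseline_log_odds +
      as.vector(g %*% config$per_snp_log_or)
    y <- stats::rbinom(block, 1L, stats::plogis(eta))
    if (n_cases < need_cases && any(y == 1L)) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L), need_cases - n_cases))]
      got_cases[[length(got_cases) + 1L]] <- g[take, , drop = FALSE]
      n_cases <- n_cases + length(take)
    }
    if (n_controls < need_controls && any(y == 0L)) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                         need_controls - n_controls))]
      got_controls[[length(got_controls) + 1L]] <- g[take, , drop = FALSE]
      n_controls <- n_controls + length(take)
    }
  }
  g <- rbind(do.call(rbind, got_cases), do.call(rbind, got_controls))
  case <- rep(c(1L, 0L), c(need_cases, need_controls))
  n <- nrow(g)
  demo <- scheme_demographics(config$covariate_scheme)
  sex <- factor(ifelse(stats::runif(n) < demo$p_male, "male", "female"),
                levels = c("female", "male"))
  age <- round(stats::rnorm(n, demo$age_mean, demo$age_sd), 1)

  # latent pigmentation: shared PRS component per trait + independent noise
  score <- as.vector(g %*% panel$weight)
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else rep(0, n)
  r2 <- config$pigmentation_r2
  traits <- scheme_traits(config$covariate_scheme)
  trait_cols <- list(skin_color = NULL, eye_color = NULL,
                     hair_color = NULL, tanning_ability = NULL)
  for (nm in names(trait_cols)) {
    if (!is.null(traits[[nm]])) {
      latent <- sqrt(r2) * z + sqrt(1 - r2) * stats::rnorm(n)
      trait_cols[[nm]] <- cut_latent(latent, traits[[nm]])
    } else {
      trait_cols[[nm]] <- factor(rep(NA_character_, n))
    }
  }
  family_history <- if (is.na(demo$fh_case)) rep(NA_integer_, n) else
    stats::rbinom(n, 1L, ifelse(case == 1L, demo$fh_case, demo$fh_control))

  out <- data.frame(
    study = config$covariate_scheme,
    id = sprintf("%s_%05d", config$covariate_scheme, seq_len(n)),
    case = case, sex = sex, age = age,
    skin_color = trait_cols$skin_color,
    eye_color = trait_cols$eye_color,
    hair_color = trait_cols$hair_color,
    tanning_ability = trait_cols$tanning_ability,
    family_history = family_history,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(g))
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "panel") <- panel
  out
}

#' Simulate the three-study ensemble
#'
#' Generates the three cohorts the analysis emulates, with their default
#' sizes and covariate schemes: a case-control discovery study with full
#' pigmentation data (1,804 cases / 1,025 controls, both sexes), an
#' all-female cohort (317 / 3,376) and an all-male cohort (177 / 2,251).
#' Per-study seeds are derived deterministically from the master seed.
#'
#' @param master_seed integer seed for the ensemble.
#' @param panel a [snp_panel].
#' @param sizes named list of `c(n_cases, n_controls)` per study; defaults
#'   to the published sizes.
#' @param ... further arguments passed to [cohort_config()] (e.g.
#'   `per_snp_log_or`, `baseline_log_odds`, `pigmentation_r2`).
#' @return Named list of three `cohort_table`s: `mdacc`, `nhs`, `hpfs`.
#' @export
simulate_three_studies <- function(master_seed = 1L, panel = default_panel(),
                                   sizes = list(mdacc = c(1804L, 1025L),
                                                nhs = c(317L, 3376L),
                                                hpfs = c(177L, 2251L)),
                                   ...) {
  stopifnot(setequal(names(sizes), SCHEMES))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(SCHEMES))
  out <- lapply(seq_along(SCHEMES), function(i) {
    s <- SCHEMES[i]
    cfg <- cohort_config(n_cases = sizes[[s]][1], n_controls = sizes[[s]][2],
                         panel = panel, covariate_scheme = s,
                         seed = seeds[i], ...)
    simulate_case_control(cfg)
  })
  names(out) <- SCHEMES
  out
}

#' Extract the dosage matrix from a cohort table
#'
#' @param cohort a `cohort_table` (or any data.frame with dosage columns).
#' @param panel the [snp_panel] naming the dosage columns.
#' @return Integer matrix of dosages, one column per panel SNP.
#' @export
dosage_matrix <- function(cohort, panel) {
  missing_cols <- setdiff(panel$snp_id, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks dosage columns for: ",
         paste(missing_cols, collapse = ", "))
  as.matrix(cohort[, panel$snp_id, drop = FALSE])
}
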
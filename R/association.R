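effect_row <- function(label, log_or, se, n_used, model_spec,
                       converged = TRUE) {
  data.frame(
    label = label,
    log_or = log_or,
    se = se,
    or_point = exp(log_or),
    ci_low = exp(log_or - Z975 * se),
    ci_high = exp(log_or + Z975 * se),
    p = 2 * stats::pnorm(-abs(log_or / se)),
    n_used = n_used,
    model_spec = model_spec,
    converged = converged,
    stringsAsFactors = FALSE
  )
}

#' Fit a logistic regression and return Wald effect estimates
#'
#' Maximum-likelihood logistic fit via [stats::glm()]; one row per
#' non-intercept coefficient with the log-OR, its Wald standard error
#' from the observed information, the exponentiated point estimate and
#' 95% CI, and the two-sided Wald p-value. Non-convergence or apparent
#' separation (runaway coefficients) raises an error rather than
#' returning a silently unstable estimate.
#'
#' @param outcome binary 0/1 vector with at least one event and one
#'   non-event.
#' @param design data.frame of predictors; factors are expanded to
#'   indicator columns by the usual treatment contrasts.
#' @param model_spec free-text description recorded with each estimate.
#' @param check `"error"` (default) aborts on runaway coefficients;
#'   `"warn"` downgrades that diagnostic to a warning naming the affected
#'   coefficients, which is appropriate when sparse nuisance-covariate
#'   cells should not abort an otherwise stable fit. Non-convergence is
#'   always an error.
#' @return A `data.frame` of effect estimates (one per coefficient).
#' @export
fit_logistic <- function(outcome, design, model_spec = NULL,
                         check = c("error", "warn")) {
  check <- match.arg(check)
  stopifnot(all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2)
    stop("outcome needs at least one event and one non-event")
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(outcome))
  dat <- cbind(.y = outcome, design)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  if (!fit$converged)
    stop("logistic model did not converge")
  coefs <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit)))
    stop("design is rank deficient: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  runaway <- abs(coefs[, "Estimate"]) > 10
  if (any(runaway)) {
    msg <- paste0("apparent separation: coefficient magnitude exceeds 10 ",
                  "on the log-odds scale for ",
                  paste(rownames(coefs)[runaway], collapse = ", "))
    if (check == "error") stop(msg) else warning(msg)
  }
  keep <- rownames(coefs) != "(Intercept)"
  if (is.null(model_spec))
    model_spec <- paste("outcome ~", paste(names(design), collapse = " + "))
  out <- effect_row(rownames(coefs)[keep], coefs[keep, "Estimate"],
                    coefs[keep, "Std. Error"], stats::nobs(fit), model_spec)
  attr(out, "fit") <- fit
  out
}

#' Unadjusted per-SNP additive association
#'
#' Fits `case ~ dosage` for one SNP: the additive (per-risk-allele) log
#' odds ratio with no covariate adjustment.
#'
#' @param cohort a `cohort_table`.
#' @param snp_id SNP to test (must be a dosage column).
#' @param panel optional [snp_panel] for validation of the dosage column.
#' @return One effect-estimate row.
#' @export
single_snp_association <- function(cohort, snp_id, panel = NULL) {
  if (!snp_id %in% names(cohort))
    stop("no dosage column for SNP ", snp_id)
  g <- cohort[[snp_id]]
  if (!all(is.na(g) | g %in% c(0, 1, 2)))
    stop("dosages for ", snp_id, " must be 0/1/2 or missing")
  ok <- !is.na(g) & !is.na(cohort$case)
  if (length(unique(g[ok])) < 2)
    stop("SNP ", snp_id, " is monomorphic in this cohort")
  est <- fit_logistic(cohort$case[ok], data.frame(dosage = g[ok]),
                      model_spec = paste0("case ~ ", snp_id, " (additive, unadjusted)"))
  est$label <- snp_id
  est
}

#' PRS-melanoma association models
#'
#' Fits the PRS association in one of four forms: `continuous` (per-unit
#' PRS), `tertile31` (top vs bottom tertile, middle tertile retained in
#' the fit via indicator coding), `band` (>=15 vs <=6 risk alleles,
#' middle band retained) or `top5pct` (above vs below the 95th PRS
#' percentile). With `adjust = TRUE` the study scheme's covariates are
#' entered exactly: mdacc adjusts for sex, age, skin, eye and hair color
#' and tanning ability; nhs for age, hair color, tanning ability and
#' family history; hpfs for age, hair and eye color and family history.
#' Categorical covariates enter as indicator sets; age is linear in
#' years. Rows with missing covariates are dropped listwise and `n_used`
#' records the fitted count.
#'
#' @param cohort a `cohort_table` (its `study` column names the scheme).
#' @param prs a `prs_result` from [compute_prs()], row-aligned to `cohort`.
#' @param form one of `"continuous"`, `"tertile31"`, `"band"`, `"top5pct"`.
#' @param adjust adjust for the scheme's covariates?
#' @return One effect-estimate row for the PRS contrast of interest.
#' @export
prs_association <- function(cohort, prs,
                            form = c("continuous", "tertile31", "band",
                                     "top5pct"),
                            adjust = FALSE) {
  form <- match.arg(form)
  stopifnot(nrow(cohort) == nrow(prs))
  scheme <- as.character(cohort$study[1])
  pred <- switch(form,
    continuous = data.frame(prs = prs$weighted_score),
    tertile31 = data.frame(prs = prs$tertile),
    band = data.frame(prs = prs$allele_band),
    top5pct = data.frame(prs = prs$top5pct))
  target <- switch(form, continuous = "prs", tertile31 = "prsT3",
                   band = paste0("prs", levels(prs$allele_band)[3]),
                   top5pct = "prs")
  dat <- cbind(case = cohort$case, pred)
  covs <- character(0)
  if (adjust) {
    covs <- scheme_covariates(scheme)
    for (cv in covs) {
      col <- cohort[[cv]]
      if (all(is.na(col)))
        stop("covariate '", cv, "' is unavailable under scheme '", scheme, "'")
      dat[[cv]] <- col
    }
    # single-sex cohorts carry no sex information to adjust on
    if ("sex" %in% covs && length(unique(stats::na.omit(dat$sex))) < 2)
      dat$sex <- NULL
    dat <- droplevels(dat)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  spec <- sprintf("case ~ PRS(%s)%s [scheme %s]", form,
                  if (adjust) paste0(" + ", paste(covs, collapse = " + "))
                  else " (unadjusted)", scheme)
  est <- withCallingHandlers(
    fit_logistic(dat$case, dat[, -1, drop = FALSE], model_spec = spec,
                 check = "warn"),
    warning = function(w) {
      # sparse nuisance cells are tolerable; instability of the PRS term
      # itself is caught below
      if (grepl("apparent separation", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  row <- est[est$label == target, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("could not locate PRS contrast '", target, "' among coefficients: ",
         paste(est$label, collapse = ", "))
  if (!is.finite(row$se) || row$se > 10 || abs(row$log_or) > 10)
    stop("PRS estimate is unstable (apparent separation) for form '",
         form, "'")
  row$label <- paste0("prs_", form)
  rownames(row) <- NULL
  row
}

#' Proportion of an ordinal trait's variation explained by the PRS
#'
#' Squared Pearson correlation between the weighted score and the
#' trait's ordinal integer coding (factor level order). This is the
#' convention used to quantify how much of the pigmentation phenotype
#' the genetic score carries.
#'
#' @param prs_scores numeric PRS values.
#' @param ordinal_trait factor or integer-coded ordinal trait.
#' @return Proportion in \[0, 1\].
#' @export
variance_explained <- function(prs_scores, ordinal_trait) {
  x <- as.numeric(if (is.factor(ordinal_trait)) unclass(ordinal_trait)
                  else ordinal_trait)
  ok <- !is.na(x) & !is.na(prs_scores)
  if (sum(ok) < 3) stop("too few complete observations")
  if (stats::sd(x[ok]) == 0) stop("trait is constant")
  stats::cor(prs_scores[ok], x[ok])^2
}
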
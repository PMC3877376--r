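# DeLong structural components via midranks: V10[i] is the placement of
# case i among the controls (ties half-credited), V01[j] the complement
# for control j; mean(V10) = mean(V01) = AUC.
delong_components <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)), !anyNA(scores))
  is_case <- labels == 1
  m <- sum(is_case); n <- sum(!is_case)
  if (m == 0 || n == 0)
    stop("both classes must be present to compute an AUC")
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[is_case], ties.method = "average")
  r_ctrl <- rank(scores[!is_case], ties.method = "average")
  v10 <- (r_all[is_case] - r_case) / n
  v01 <- 1 - (r_all[!is_case] - r_ctrl) / m
  list(auc = (sum(r_all[is_case]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01, m = m, n = n)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen case scores higher than a
#' randomly chosen control, with ties contributing 1/2. Computed from
#' midranks, which is exactly the exhaustive pairwise comparison count.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (1 = case).
#' @param ci if `TRUE`, also return the DeLong standard error and 95% CI.
#' @return The AUC, or (with `ci = TRUE`) a list with `auc`, `se`, `ci95`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1
roc_auc <- function(scores, labels, ci = FALSE) {
  d <- delong_components(scores, labels)
  if (!ci) return(d$auc)
  se <- sqrt(stats::var(d$v10) / d$m + stats::var(d$v01) / d$n)
  list(auc = d$auc, se = se,
       ci95 = pmin(1, pmax(0, d$auc + c(-1, 1) * Z975 * se)))
}

#' Paired AUC contrast (DeLong test)
#'
#' Compares the AUCs of two risk scores evaluated on the same
#' individuals. The variance of the AUC difference uses the paired
#' DeLong covariance of the structural components, so the correlation
#' induced by scoring the same subjects is accounted for.
#'
#' @param scores_a,scores_b paired score vectors (same individuals, same
#'   order).
#' @param labels binary outcome (1 = case).
#' @return List with `auc_a`, `auc_b`, `delta` (a - b), `se`, `ci95`,
#'   `z`, `p` (two-sided).
#' @export
auc_contrast <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be paired (equal length)")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  delta <- da$auc - db$auc
  se <- sqrt(max(v, 0))
  z <- if (se == 0 && delta == 0) 0 else delta / se
  list(auc_a = da$auc, auc_b = db$auc, delta = delta, se = se,
       ci95 = delta + c(-1, 1) * Z975 * se,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fit the five-model risk-prediction suite
#'
#' The five nested/alternative logistic models whose discrimination is
#' compared on the discovery-style cohort: (1) the single index SNP's
#' dosage, (2) the PRS alone, (3) sex and age, (4) sex, age and
#' pigmentation (skin, eye and hair color, tanning ability), and (5)
#' model 4 plus the PRS. All five are fit on the identical complete-case
#' subset of the richest model so AUC contrasts are paired.
#'
#' @param cohort an mdacc-scheme `cohort_table` (full pigmentation data).
#' @param prs a `prs_result` row-aligned to `cohort`.
#' @param index_snp the single-SNP model's SNP (default `rs12913832`).
#' @return An object of class `risk_model_suite`: list with `summary`
#'   (model, n, AUC, CI), `probs` (n x 5 matrix of fitted probabilities),
#'   `contrasts` (paired DeLong tests 2-1, 4-3, 5-4), `labels`, `n_used`,
#'   and `kept` (row indices of `cohort` retained as complete cases).
#' @export
build_model_suite <- function(cohort, prs, index_snp = "rs12913832") {
  if (!index_snp %in% names(cohort))
    stop("index SNP ", index_snp, " has no dosage column")
  pig <- c("skin_color", "eye_color", "hair_color", "tanning_ability")
  missing_pig <- pig[vapply(pig, function(v) all(is.na(cohort[[v]])),
                            logical(1))]
  if (length(missing_pig))
    stop("pigmentation covariates unavailable: ",
         paste(missing_pig, collapse = ", "),
         "; models 4 and 5 cannot be fit under this scheme")
  dat <- data.frame(case = cohort$case,
                    snp = cohort[[index_snp]],
                    prs = prs$weighted_score,
                    sex = cohort$sex, age = cohort$age,
                    cohort[pig])
  kept <- which(stats::complete.cases(dat))
  dat <- droplevels(dat[kept, , drop = FALSE])
  model_vars <- list(
    single_snp = "snp",
    prs_only = "prs",
    sex_age = c("sex", "age"),
    sex_age_pigment = c("sex", "age", pig),
    sex_age_pigment_prs = c("sex", "age", pig, "prs"))
  probs <- matrix(NA_real_, nrow(dat), length(model_vars),
                  dimnames = list(NULL, names(model_vars)))
  auc <- vector("list", length(model_vars))
  for (i in seq_along(model_vars)) {
    est <- fit_logistic(dat$case, dat[, model_vars[[i]], drop = FALSE],
                        model_spec = paste("case ~",
                                           paste(model_vars[[i]],
                                                 collapse = " + ")),
                        check = "warn")
    probs[, i] <- stats::fitted(attr(est, "fit"))
    auc[[i]] <- roc_auc(probs[, i], dat$case, ci = TRUE)
  }
  contrasts <- list(
    prs_vs_single_snp = auc_contrast(probs[, "prs_only"],
                                     probs[, "single_snp"], dat$case),
    pigment_vs_sex_age = auc_contrast(probs[, "sex_age_pigment"],
                                      probs[, "sex_age"], dat$case),
    prs_added_vs_pigment = auc_contrast(probs[, "sex_age_pigment_prs"],
                                        probs[, "sex_age_pigment"],
                                        dat$case))
  summary <- data.frame(
    model = names(model_vars),
    n = nrow(dat),
    auc = vapply(auc, `[[`, numeric(1), "auc"),
    auc_low = vapply(auc, function(a) a$ci95[1], numeric(1)),
    auc_high = vapply(auc, function(a) a$ci95[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, probs = probs, contrasts = contrasts,
                 labels = dat$case, n_used = nrow(dat), kept = kept),
            class = "risk_model_suite")
}

#' @export
print.risk_model_suite <- function(x, ...) {
  cat(sprintf("Risk model suite on %d complete cases\n", x$n_used))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s AUC %.3f (%.3f-%.3f)\n",
                s$model[i], s$auc[i], s$auc_low[i], s$auc_high[i]))
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %-22s dAUC %.3f (%.3f-%.3f), p = %.3g\n",
                nm, ct$delta, ct$ci95[1], ct$ci95[2], ct$p))
  }
  invisible(x)
}

#' ROC curve coordinates
#'
#' Sensitivity/1-specificity pairs over all score thresholds, for
#' plotting or export.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (1 = case).
#' @return `data.frame` with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores, labels) {
  stopifnot(all(labels %in% c(0, 1)))
  thr <- sort(unique(scores), decreasing = TRUE)
  m <- sum(labels == 1); n <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / m,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n,
                 numeric(1))
  data.frame(threshold = c(Inf, thr), sensitivity = c(0, sens),
             specificity = c(1, spec))
}
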
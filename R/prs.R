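check_dosages <- function(dosages, panel) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel))
    stop("dosage matrix has ", ncol(dosages), " columns but panel has ",
         nrow(panel), " SNPs")
  if (!is.null(colnames(dosages)) &&
      !identical(sort(colnames(dosages)), sort(panel$snp_id)))
    stop("dosage column names do not match panel snp_id")
  if (!is.null(colnames(dosages)))
    dosages <- dosages[, panel$snp_id, drop = FALSE]
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or missing")
  dosages
}

#' Count risk alleles per individual
#'
#' Sums each individual's risk-allele dosages over the non-missing SNPs
#' of the panel.
#'
#' @param dosages matrix of dosages (individuals x SNPs), values in
#'   \{0, 1, 2\} or `NA`.
#' @param panel the [snp_panel] the columns conform to.
#' @return Integer vector of risk-allele counts.
#' @export
count_risk_alleles <- function(dosages, panel) {
  dosages <- check_dosages(dosages, panel)
  as.integer(rowSums(dosages, na.rm = TRUE))
}

#' Weighted polygenic risk score
#'
#' The PRS is the inner product of an individual's risk-allele dosages
#' with the panel's log-odds weights: `score_i = sum_j w_j * g_ij`.
#' Missing dosages are handled by `missing_policy`: `"mean"` imputes the
#' population mean dosage `2 * risk_allele_freq` for that SNP; `"drop"`
#' leaves the score `NA` for any individual with a missing dosage so
#' downstream model fits exclude them. Individuals with every dosage
#' missing get an `NA` score under either policy.
#'
#' @param dosages matrix of dosages (individuals x SNPs).
#' @param panel the [snp_panel] supplying weights and frequencies.
#' @param missing_policy `"mean"` (default) or `"drop"`.
#' @return Numeric vector of scores (log-odds units).
#' @export
weighted_prs <- function(dosages, panel, missing_policy = c("mean", "drop")) {
  missing_policy <- match.arg(missing_policy)
  dosages <- check_dosages(dosages, panel)
  n_miss <- rowSums(is.na(dosages))
  if (missing_policy == "mean") {
    for (j in seq_len(ncol(dosages))) {
      na <- is.na(dosages[, j])
      if (any(na)) dosages[na, j] <- 2 * panel$risk_allele_freq[j]
    }
    score <- as.vector(dosages %*% panel$weight)
    score[n_miss == ncol(dosages)] <- NA_real_
  } else {
    score <- as.vector(dosages %*% panel$weight) # NA propagates
  }
  score
}

#' Assign PRS tertile labels against a reference distribution
#'
#' Cutpoints are the 1/3 and 2/3 quantiles of `reference_scores`
#' (quantile type 7, linear interpolation between order statistics, so
#' labels are bit-reproducible). An individual is `T1` if its score is
#' `<=` the lower cutpoint, `T3` if strictly above the upper cutpoint,
#' else `T2`; scores outside the reference range fall into the outer
#' tertiles.
#'
#' @param scores scores to label.
#' @param reference_scores scores defining the cutpoints (default: the
#'   analysis sample itself, i.e. cases plus controls).
#' @return Factor with levels `T1`, `T2`, `T3`.
#' @export
categorize_tertiles <- function(scores, reference_scores = scores) {
  ref <- reference_scores[!is.na(reference_scores)]
  if (!length(ref)) stop("reference_scores is empty")
  q <- stats::quantile(ref, c(1, 2) / 3, type = 7, names = FALSE)
  if (q[1] == q[2])
    stop("degenerate tertiles: reference quantiles coincide")
  lab <- ifelse(scores <= q[1], "T1", ifelse(scores <= q[2], "T2", "T3"))
  factor(lab, levels = c("T1", "T2", "T3"))
}

#' Band individuals by total risk-allele count
#'
#' Three bands: `<= low`, the middle range, and `>= high` risk alleles
#' (defaults reproduce the <=6 / 7-14 / >=15 grouping).
#'
#' @param counts non-negative integer allele counts.
#' @param low,high band boundaries (`low < high - 1`).
#' @return Factor with levels `"<=low"`, `"(low+1)-(high-1)"`, `">=high"`.
#' @export
band_by_allele_count <- function(counts, low = 6L, high = 15L) {
  stopifnot(all(counts >= 0, na.rm = TRUE), low < high - 1L)
  levs <- c(paste0("<=", low), paste0(low + 1L, "-", high - 1L),
            paste0(">=", high))
  lab <- ifelse(counts <= low, levs[1], ifelse(counts >= high, levs[3], levs[2]))
  factor(lab, levels = levs)
}

#' Flag scores above a percentile threshold
#'
#' Indicator of a score strictly above the `q` quantile (type 7) of the
#' analysis sample; with `q = 0.95` this splits off the top 5% of the
#' PRS distribution.
#'
#' @param scores PRS values.
#' @param q percentile in (0, 1); default 0.95.
#' @return Integer 0/1 vector (`NA` scores stay `NA`).
#' @export
split_at_percentile <- function(scores, q = 0.95) {
  s <- scores[!is.na(scores)]
  if (!length(s)) stop("no non-missing scores")
  thr <- stats::quantile(s, q, type = 7, names = FALSE)
  as.integer(scores > thr)
}

#' Per-individual PRS result
#'
#' Convenience wrapper computing the allele count, weighted score and the
#' three published groupings (tertiles, allele-count bands, top-5% split)
#' in one pass.
#'
#' @param cohort a `cohort_table` or a dosage matrix.
#' @param panel the [snp_panel].
#' @param missing_policy passed to [weighted_prs()].
#' @param reference_scores optional external reference for the tertile
#'   cutpoints; default is the sample itself.
#' @return A `data.frame` of class `prs_result` with columns
#'   `total_risk_alleles`, `weighted_score`, `n_missing_snps`, `tertile`,
#'   `allele_band`, `top5pct`.
#' @export
compute_prs <- function(cohort, panel, missing_policy = c("mean", "drop"),
                        reference_scores = NULL) {
  missing_policy <- match.arg(missing_policy)
  dosages <- if (is.data.frame(cohort)) dosage_matrix(cohort, panel)
             else cohort
  dosages <- check_dosages(dosages, panel)
  score <- weighted_prs(dosages, panel, missing_policy)
  if (is.null(reference_scores)) reference_scores <- score
  out <- data.frame(
    total_risk_alleles = count_risk_alleles(dosages, panel),
    weighted_score = score,
    n_missing_snps = rowSums(is.na(dosages)),
    tertile = categorize_tertiles(score, reference_scores),
    allele_band = band_by_allele_count(count_risk_alleles(dosages, panel)),
    top5pct = split_at_percentile(score)
  )
  class(out) <- c("prs_result", "data.frame")
  out
}
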
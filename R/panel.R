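#' Construct a SNP panel
#'
#' A SNP panel holds the per-SNP metadata the PRS and the simulator need:
#' identifier, risk allele, log-odds weight and risk-allele frequency.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param risk_allele single-character nucleotide per SNP (`A`,`C`,`G`,`T`).
#' @param weight numeric log-odds weight per risk allele; must be finite.
#' @param risk_allele_freq numeric risk-allele frequency, strictly in (0, 1).
#' @param gene optional gene label per SNP (annotation only).
#'
#' @return A `data.frame` of class `snp_panel` with one row per SNP.
#' @export
#' @examples
#' snp_panel("rs1", "A", log(1.3), 0.25)
snp_panel <- function(snp_id, risk_allele, weight, risk_allele_freq,
                      gene = NA_character_) {
  snp_id <- as.character(snp_id)
  risk_allele <- toupper(as.character(risk_allele))
  if (anyDuplicated(snp_id))
    stop("snp_id values must be unique")
  if (!all(risk_allele %in% c("A", "C", "G", "T")))
    stop("risk_allele must be a single nucleotide (A/C/G/T)")
  if (!all(is.finite(weight)))
    stop("panel weights must be finite")
  if (!all(risk_allele_freq > 0 & risk_allele_freq < 1))
    stop("risk_allele_freq must be strictly inside (0, 1)")
  out <- data.frame(
    snp_id = snp_id,
    risk_allele = risk_allele,
    weight = as.numeric(weight),
    risk_allele_freq = as.numeric(risk_allele_freq),
    gene = rep_len(as.character(gene), length(snp_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Default 11-SNP melanoma susceptibility panel
#'
#' Eleven SNPs previously associated with melanoma risk, one per gene
#' region (chosen to minimize linkage disequilibrium). Frequencies are the
#' published minor-allele frequencies, taken as risk-allele frequencies;
#' for some SNPs the risk allele may in truth be the major allele — the
#' published tables do not disambiguate, so this default is a single
#' self-consistent convention that callers can override per SNP. Weights
#' are the natural logs of the pooled three-study odds ratios, a stand-in
#' for the original prior-study risk coefficients (not publicly printed);
#' both columns are plain data and can be replaced.
#'
#' @return A [snp_panel] with 11 rows.
#' @export
default_panel <- function() {
  tab <- published_or_table()
  pooled <- tab[tab$study == "pooled", c("snp_id", "or")]
  meta <- data.frame(
    snp_id = c("rs7412746", "rs13016963", "rs4636294", "rs1335510",
               "rs7023329", "rs10830253", "rs1801516", "rs12913832",
               "rs258322", "rs4911442", "rs132985"),
    risk_allele = c("T", "A", "A", "T", "A", "G", "G", "G", "A", "G", "C"),
    freq = c(0.4452, 0.3834, 0.4781, 0.3919, 0.4696, 0.3398, 0.1333,
             0.2250, 0.1203, 0.1506, 0.4518),
    gene = c("ARNT", "ALS2CR12", "LOC402359", "LOC100418", "MTAP", "TYR",
             "ATM", "HERC2", "CDK10", "ASIP", "PLA2G6"),
    stringsAsFactors = FALSE
  )
  w <- log(pooled$or[match(meta$snp_id, pooled$snp_id)])
  snp_panel(meta$snp_id, meta$risk_allele, w, meta$freq, meta$gene)
}

#' Published per-study and pooled odds ratios for the 11-SNP panel and PRS
#'
#' The per-study and pooled OR (95% CI) entries reported for each of the
#' 11 panel SNPs (unadjusted additive models) and for the PRS association
#' models (per-unit continuous and tertile-3-vs-tertile-1, univariate and
#' multivariate). These printed summary estimates are the inputs to the
#' meta-analysis reproduction: individual-level study data were never
#' deposited.
#'
#' @return A `data.frame` with columns `snp_id` (SNP rsID or a PRS model
#'   label), `study` (`mdacc`, `nhs`, `hpfs`, `pooled`), `or`, `ci_low`,
#'   `ci_high`.
#' @export
published_or_table <- function() {
  # columns: label, mdacc OR/lo/hi, nhs OR/lo/hi, hpfs OR/lo/hi, pooled OR/lo/hi
  raw <- list(
    c("rs7412746",  1.18,1.06,1.31, 1.24,1.04,1.46, 0.97,0.78,1.21, 1.15,1.02,1.29),
    c("rs13016963", 1.13,1.01,1.26, 1.04,0.88,1.23, 0.78,0.62,0.98, 0.99,0.81,1.20),
    c("rs4636294",  1.23,1.10,1.37, 1.00,0.85,1.18, 1.08,0.87,1.33, 1.11,0.97,1.28),
    c("rs1335510",  1.26,1.12,1.40, 1.03,0.87,1.21, 1.03,0.83,1.28, 1.12,0.96,1.30),
    c("rs7023329",  1.26,1.13,1.41, 1.01,0.85,1.18, 1.11,0.90,1.38, 1.13,0.97,1.32),
    c("rs10830253", 1.19,1.06,1.33, 1.27,1.07,1.50, 1.54,1.24,1.92, 1.29,1.12,1.48),
    c("rs1801516",  1.23,1.05,1.44, 1.16,0.92,1.48, 0.84,0.62,1.14, 1.10,0.89,1.34),
    c("rs12913832", 1.43,1.26,1.62, 1.23,1.01,1.49, 1.12,0.88,1.43, 1.29,1.12,1.48),
    c("rs258322",   1.54,1.29,1.84, 1.62,1.28,2.05, 1.28,0.90,1.82, 1.53,1.34,1.74),
    c("rs4911442",  1.27,1.08,1.49, 1.30,1.03,1.65, 1.32,0.96,1.83, 1.28,1.14,1.45),
    c("rs132985",   1.20,1.08,1.34, 1.12,0.95,1.32, 1.20,0.96,1.49, 1.18,1.08,1.28),
    c("prs_continuous_univariate",   1.19,1.15,1.24, 1.13,1.08,1.19, 1.10,1.03,1.18, 1.15,1.09,1.20),
    c("prs_continuous_multivariate", 1.17,1.12,1.22, 1.10,1.04,1.16, 1.07,1.00,1.15, 1.12,1.06,1.18),
    c("prs_tertile31_univariate",    2.34,1.93,2.84, 1.73,1.30,2.30, 1.54,1.06,2.24, 1.90,1.46,2.48),
    c("prs_tertile31_multivariate",  2.13,1.69,2.68, 1.55,1.14,2.11, 1.34,0.90,2.00, 1.69,1.28,2.25)
  )
  studies <- c("mdacc", "nhs", "hpfs", "pooled")
  rows <- lapply(raw, function(r) {
    data.frame(
      snp_id = r[[1]],
      study = studies,
      or = as.numeric(r[c(2, 5, 8, 11)]),
      ci_low = as.numeric(r[c(3, 6, 9, 12)]),
      ci_high = as.numeric(r[c(4, 7, 10, 13)]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Published reclassification counts (conventional model vs model plus PRS)
#'
#' The 3x3 cross-tabulations of predicted-risk categories (<20%, 20-50%,
#' >=50%) under the conventional phenotypic model (rows) versus the model
#' additionally including the PRS (columns), separately for melanoma
#' patients (events) and controls (non-events), as published for the
#' discovery study.
#'
#' @return A list with `events` and `nonevents`, each a 3x3 integer matrix
#'   with dimnames `old` x `new` over `c("<20%","20-50%",">=50%")`.
#' @export
published_reclassification_counts <- function() {
  cats <- c("<20%", "20-50%", ">=50%")
  events <- matrix(c(0, 0, 0,
                     0, 372, 306,
                     0, 86, 1039),
                   nrow = 3, byrow = TRUE, dimnames = list(old = cats, new = cats))
  nonevents <- matrix(c(0, 0, 0,
                        4, 579, 231,
                        0, 113, 99),
                      nrow = 3, byrow = TRUE, dimnames = list(old = cats, new = cats))
  list(events = events, nonevents = nonevents)
}
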
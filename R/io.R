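#' Write a cohort table as TSV
#'
#' One row per individual, one dosage column per SNP; factors are written
#' as their labels, missing values as `NA`. Numeric columns use full
#' precision so a write/read round trip is lossless.
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (j in names(out))
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort table from TSV
#'
#' Inverse of [write_cohort_tsv()]: re-establishes the factor levels of
#' the categorical covariates from the scheme layouts so round trips are
#' exact.
#'
#' @param path TSV file written by [write_cohort_tsv()].
#' @return A `cohort_table`.
#' @export
read_cohort_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  scheme <- out$study[1]
  out$sex <- factor(out$sex, levels = c("female", "male"))
  traits <- scheme_traits(scheme)
  for (nm in c("skin_color", "eye_color", "hair_color", "tanning_ability")) {
    levs <- if (!is.null(traits[[nm]])) traits[[nm]]$levels else character(0)
    out[[nm]] <- factor(out[[nm]], levels = levs)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read a SNP panel from TSV/CSV/JSON/YAML
#'
#' Expects fields `snp_id`, `risk_allele`, `weight`, `risk_allele_freq`
#' (and optionally `gene`); the format is inferred from the file
#' extension.
#'
#' @param path panel file.
#' @return A [snp_panel].
#' @export
read_panel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    tsv = utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    yaml = ,
    yml = as.data.frame(lapply(yaml::read_yaml(path), unlist),
                        stringsAsFactors = FALSE),
    stop("unsupported panel format: .", ext))
  need <- c("snp_id", "risk_allele", "weight", "risk_allele_freq")
  if (!all(need %in% names(tab)))
    stop("panel file must provide columns: ", paste(need, collapse = ", "))
  snp_panel(tab$snp_id, tab$risk_allele, as.numeric(tab$weight),
            as.numeric(tab$risk_allele_freq),
            gene = if ("gene" %in% names(tab)) tab$gene else NA_character_)
}

#' Write a SNP panel
#'
#' @param panel a [snp_panel].
#' @param path output path; `.tsv`, `.csv`, `.json` or `.yaml` by
#'   extension.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  ext <- tolower(tools::file_ext(path))
  tab <- as.data.frame(panel)
  switch(ext,
    tsv = utils::write.table(tab, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
    csv = utils::write.csv(tab, path, row.names = FALSE),
    json = jsonlite::write_json(tab, path, digits = NA, pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(lapply(tab, function(x) as.vector(x)), path,
                           precision = 15),
    stop("unsupported panel format: .", ext))
  invisible(path)
}

#' Read genotype dosages from TSV or VCF, oriented to the risk allele
#'
#' TSV input is a plain dosage table (one column per SNP, values 0/1/2
#' or `NA`). VCF input must contain biallelic SNP records with a `GT`
#' field; each record's ID is matched to the panel, and the dosage is
#' the count of the panel's risk allele: the ALT count if the risk
#' allele is ALT, `2 - ALT count` if it is REF. A record whose alleles
#' match neither is a hard error naming the SNP.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (default: by extension).
#' @param panel the [snp_panel] to orient against.
#' @return Integer dosage matrix with columns in panel order.
#' @export
read_genotypes <- function(path, format = NULL, panel) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, na.strings = c("NA", "."))
    g <- as.matrix(tab[, intersect(names(tab), panel$snp_id), drop = FALSE])
    storage.mode(g) <- "integer"
    return(check_dosages(g, panel))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record VCF
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  ids <- fix[, "ID"]
  keep <- match(panel$snp_id, ids)
  if (anyNA(keep))
    stop("VCF lacks records for: ",
         paste(panel$snp_id[is.na(keep)], collapse = ", "))
  n <- ncol(gt)
  out <- matrix(NA_integer_, n, nrow(panel),
                dimnames = list(colnames(gt), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    i <- keep[j]
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (is.na(alt) || grepl(",", alt))
      stop("VCF record for ", panel$snp_id[j], " is not biallelic")
    alt_count <- vapply(gt[i, ], function(x) {
      if (is.na(x)) return(NA_integer_)
      al <- strsplit(x, "[/|]")[[1]]
      if (any(al == ".")) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
    ra <- panel$risk_allele[j]
    if (ra == alt) out[, j] <- alt_count
    else if (ra == ref) out[, j] <- 2L - alt_count
    else stop("risk allele ", ra, " for ", panel$snp_id[j],
              " matches neither REF (", ref, ") nor ALT (", alt, ")")
  }
  out
}

#' Write panel genotypes as a minimal biallelic VCF
#'
#' Emits one biallelic SNP record per panel entry with genotypes encoded
#' so the ALT allele is the risk allele (dosage = ALT count); the risk
#' allele is also recorded in the `RA` INFO tag. The analysis is
#' position-agnostic, so positions are synthetic 1-based indices on a
#' placeholder contig.
#'
#' @param dosages integer dosage matrix (individuals x SNPs).
#' @param panel the [snp_panel].
#' @param path output `.vcf` path.
#' @param sample_ids optional sample names (default `S1..Sn`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosages, panel, path, sample_ids = NULL) {
  dosages <- check_dosages(dosages, panel)
  n <- nrow(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  other <- c(A = "C", C = "A", G = "A", T = "A")
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RA,Number=1,Type=String,Description=\"Risk allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  rows <- vapply(seq_len(nrow(panel)), function(j) {
    ra <- panel$risk_allele[j]
    gts <- ifelse(is.na(dosages[, j]), "./.", gt_code[dosages[, j] + 1L])
    paste(c("1", j, panel$snp_id[j], other[[ra]], ra, ".", "PASS",
            paste0("RA=", ra), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
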
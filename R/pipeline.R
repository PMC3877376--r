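#' Pipeline configuration
#'
#' @param seed master seed for the whole run (all randomness derives
#'   from it).
#' @param out_dir output directory (created if absent).
#' @param panel a [snp_panel] or a path readable by [read_panel()].
#' @param missing_policy PRS missing-dosage policy, `"mean"` or `"drop"`.
#' @param cutpoints risk-category cutpoints for reclassification.
#' @param index_snp SNP for the single-SNP discrimination model.
#' @param sizes per-study `c(n_cases, n_controls)`; default published
#'   sizes.
#' @param pigmentation_r2 PRS-pigmentation calibration for the simulator.
#' @param write_cohorts also write the three simulated cohort TSVs?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "melprs_out",
                            panel = default_panel(),
                            missing_policy = "mean",
                            cutpoints = c(0.20, 0.50),
                            index_snp = "rs12913832",
                            sizes = list(mdacc = c(1804L, 1025L),
                                         nhs = c(317L, 3376L),
                                         hpfs = c(177L, 2251L)),
                            pigmentation_r2 = 0.03,
                            write_cohorts = FALSE) {
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "snp_panel"))
  structure(list(seed = as.integer(seed), out_dir = out_dir, panel = panel,
                 missing_policy = missing_policy, cutpoints = cutpoints,
                 index_snp = index_snp, sizes = sizes,
                 pigmentation_r2 = pigmentation_r2,
                 write_cohorts = isTRUE(write_cohorts)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; recognised fields are the arguments of
#'   [pipeline_config()] (with `panel` a file path).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  if (!is.null(raw$sizes))
    raw$sizes <- lapply(raw$sizes, as.integer)
  do.call(pipeline_config, raw)
}

fmt <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
}

write_tsv_fixed <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in names(df)[num]) df[[j]] <- fmt(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pool_estimate_rows <- function(rows) {
  m <- meta_from_estimates(rows)
  data.frame(study = "pooled",
             or = m$pooled_or, ci_low = m$ci95[1], ci_high = m$ci95[2],
             p = m$p, n_used = sum(rows$n_used),
             Q = m$Q, p_Q = m$p_Q, i2 = m$i2, tau2 = m$tau2,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on simulated cohorts
#'
#' Simulates the three-study ensemble, computes per-study PRS, fits the
#' per-SNP and PRS association models, pools them by random-effects
#' meta-analysis, fits the five-model discrimination suite with paired
#' AUC contrasts on the discovery-style cohort, and compares
#' reclassification of the phenotypic model with and without the PRS.
#' Writes five summary TSVs (per-SNP associations, PRS associations,
#' model AUCs, AUC contrasts, reclassification) plus a JSON run manifest
#' (seed, package version, config hash). Given the same seed the output
#' files are byte-identical across runs.
#'
#' @param config a [pipeline_config()] (or a path to a YAML/JSON config).
#' @return Invisibly, a list with the in-memory results and the paths of
#'   the files written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- config$panel
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohorts <- stage("simulate",
    simulate_three_studies(config$seed, panel = panel, sizes = config$sizes,
                           pigmentation_r2 = config$pigmentation_r2))
  prs <- stage("prs", lapply(cohorts, compute_prs, panel = panel,
                             missing_policy = config$missing_policy))

  snp_rows <- stage("assoc_snp", do.call(rbind, lapply(panel$snp_id, function(s) {
    ests <- do.call(rbind, lapply(names(cohorts), function(st)
      single_snp_association(cohorts[[st]], s)))
    per_study <- data.frame(study = names(cohorts), or = ests$or_point,
                            ci_low = ests$ci_low, ci_high = ests$ci_high,
                            p = ests$p, n_used = ests$n_used,
                            Q = NA_real_, p_Q = NA_real_, i2 = NA_real_,
                            tau2 = NA_real_, stringsAsFactors = FALSE)
    cbind(snp_id = s, rbind(per_study, pool_estimate_rows(ests)))
  })))

  prs_rows <- stage("assoc_prs", {
    grid <- expand.grid(form = c("continuous", "tertile31"),
                        adjust = c(FALSE, TRUE), stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      form <- grid$form[i]; adj <- grid$adjust[i]
      ests <- do.call(rbind, lapply(names(cohorts), function(st)
        prs_association(cohorts[[st]], prs[[st]], form = form, adjust = adj)))
      per_study <- data.frame(study = names(cohorts), or = ests$or_point,
                              ci_low = ests$ci_low, ci_high = ests$ci_high,
                              p = ests$p, n_used = ests$n_used,
                              Q = NA_real_, p_Q = NA_real_, i2 = NA_real_,
                              tau2 = NA_real_, stringsAsFactors = FALSE)
      cbind(model = form, analysis = if (adj) "multivariate" else "univariate",
            rbind(per_study, pool_estimate_rows(ests)))
    }))
  })
  # discovery-cohort extreme-score contrasts (top 5% of PRS)
  extreme_rows <- stage("assoc_extreme", {
    ests <- rbind(
      prs_association(cohorts$mdacc, prs$mdacc, form = "top5pct",
                      adjust = FALSE),
      prs_association(cohorts$mdacc, prs$mdacc, form = "top5pct",
                      adjust = TRUE))
    data.frame(model = "top5pct",
               analysis = c("univariate", "multivariate"),
               study = "mdacc", or = ests$or_point, ci_low = ests$ci_low,
               ci_high = ests$ci_high, p = ests$p, n_used = ests$n_used,
               Q = NA_real_, p_Q = NA_real_, i2 = NA_real_, tau2 = NA_real_,
               stringsAsFactors = FALSE)
  })
  prs_rows <- rbind(prs_rows, extreme_rows)

  suite <- stage("discriminate",
    build_model_suite(cohorts$mdacc, prs$mdacc, index_snp = config$index_snp))
  contrast_rows <- do.call(rbind, lapply(names(suite$contrasts), function(nm) {
    ct <- suite$contrasts[[nm]]
    data.frame(contrast = nm, delta_auc = ct$delta, ci_low = ct$ci95[1],
               ci_high = ct$ci95[2], p = ct$p, stringsAsFactors = FALSE)
  }))

  reclass <- stage("reclassify",
    reclassification_compare(suite$probs[, "sex_age_pigment"],
                             suite$probs[, "sex_age_pigment_prs"],
                             suite$labels, cutpoints = config$cutpoints))
  reclass_rows <- data.frame(
    quantity = c("nri_events", "nonevents_up_minus_down", "total_nri",
                 "p_nri", "idi", "p_idi",
                 "up_events", "down_events", "n_events",
                 "up_nonevents", "down_nonevents", "n_nonevents"),
    value = c(reclass$nri$nri_events, reclass$nri$nonevents_up_minus_down,
              reclass$nri$total_nri, reclass$nri$p,
              reclass$idi$idi, reclass$idi$p,
              reclass$nri$up_events, reclass$nri$down_events,
              reclass$nri$n_events, reclass$nri$up_nonevents,
              reclass$nri$down_nonevents, reclass$nri$n_nonevents),
    stringsAsFactors = FALSE)

  paths <- c(
    snp_associations = file.path(config$out_dir, "snp_associations.tsv"),
    prs_associations = file.path(config$out_dir, "prs_associations.tsv"),
    model_auc = file.path(config$out_dir, "model_auc.tsv"),
    auc_contrasts = file.path(config$out_dir, "auc_contrasts.tsv"),
    reclassification = file.path(config$out_dir, "reclassification.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_tsv_fixed(snp_rows, paths["snp_associations"])
  write_tsv_fixed(prs_rows, paths["prs_associations"])
  write_tsv_fixed(suite$summary, paths["model_auc"])
  write_tsv_fixed(contrast_rows, paths["auc_contrasts"])
  write_tsv_fixed(reclass_rows, paths["reclassification"])
  if (config$write_cohorts)
    for (st in names(cohorts))
      write_cohort_tsv(cohorts[[st]],
                       file.path(config$out_dir, paste0("cohort_", st, ".tsv")))

  cfg_tmp <- tempfile(fileext = ".json")
  cfg_plain <- config
  cfg_plain$panel <- as.data.frame(config$panel)
  jsonlite::write_json(unclass(cfg_plain), cfg_tmp, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "melprs",
    version = as.character(utils::packageVersion("melprs")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    outputs = as.list(basename(paths[names(paths) != "manifest"])))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohorts = cohorts, prs = prs, snp_associations = snp_rows,
                 prs_associations = prs_rows, suite = suite,
                 reclassification = reclass, paths = paths))
}
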
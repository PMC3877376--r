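#' Assign predicted probabilities to risk categories
#'
#' Three categories at the published cutpoints: low `[0, 0.20)`,
#' intermediate `[0.20, 0.50)` and high `[0.50, 1]` — the boundary
#' probability 0.50 is assigned upward (">= 50%").
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param cutpoints two increasing cutpoints in (0, 1).
#' @return Ordered factor with levels like `"<20%"`, `"20-50%"`, `">=50%"`.
#' @export
risk_categories <- function(probabilities, cutpoints = c(0.20, 0.50)) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2],
            all(cutpoints > 0 & cutpoints < 1))
  pct <- function(x) sprintf("%g", 100 * x)
  levs <- c(paste0("<", pct(cutpoints[1]), "%"),
            paste0(pct(cutpoints[1]), "-", pct(cutpoints[2]), "%"),
            paste0(">=", pct(cutpoints[2]), "%"))
  idx <- findInterval(probabilities, cutpoints) + 1L
  factor(levs[idx], levels = levs, ordered = TRUE)
}

#' Cross-tabulate old vs new risk categories by outcome
#'
#' @param old_labels,new_labels aligned category factors (same levels)
#'   from the old and new model.
#' @param outcome binary outcome (1 = event).
#' @return List with `events` and `nonevents` square count matrices
#'   (rows = old category, columns = new), plus `n_excluded` rows dropped
#'   for missing categories.
#' @export
reclassification_tables <- function(old_labels, new_labels, outcome) {
  if (length(old_labels) != length(new_labels) ||
      length(old_labels) != length(outcome))
    stop("old_labels, new_labels and outcome must have equal length")
  stopifnot(all(outcome %in% c(0, 1), na.rm = TRUE))
  ok <- !is.na(old_labels) & !is.na(new_labels) & !is.na(outcome)
  old <- old_labels[ok]; new <- new_labels[ok]; y <- outcome[ok]
  tab <- function(sel) {
    m <- table(old = old[sel], new = new[sel])
    matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  }
  list(events = tab(y == 1), nonevents = tab(y == 0),
       n_excluded = sum(!ok))
}

movement_counts <- function(m) {
  up <- sum(m[upper.tri(m)])
  down <- sum(m[lower.tri(m)])
  c(up = up, down = down, n = sum(m))
}

#' Categorical net reclassification improvement
#'
#' From the paired events/non-events reclassification tables: the event
#' component is `(up_e - down_e) / n_e`; the non-event quantity is kept
#' in the published orientation `(up_ne - down_ne) / n_ne` (upward moves
#' of non-events are adverse), and the total NRI subtracts it:
#' `total = nri_events - nonevents_up_minus_down`. The z test follows
#' Pencina: `total / sqrt((up_e + down_e)/n_e^2 + (up_ne + down_ne)/n_ne^2)`.
#' A conventionally signed non-event component
#' `(down_ne - up_ne)/n_ne` is also returned as `nri_nonevents`.
#'
#' @param tables list with `events` and `nonevents` square count matrices
#'   (rows = old category, columns = new), as from
#'   [reclassification_tables()].
#' @return List with `nri_events`, `nonevents_up_minus_down`,
#'   `nri_nonevents`, `total_nri`, `z`, `p`, and the movement counts.
#' @export
categorical_nri <- function(tables) {
  ev <- movement_counts(tables$events)
  ne <- movement_counts(tables$nonevents)
  if (ev["n"] == 0 || ne["n"] == 0)
    stop("need at least one event and one non-event")
  nri_e <- (ev["up"] - ev["down"]) / ev["n"]
  ne_up_minus_down <- (ne["up"] - ne["down"]) / ne["n"]
  total <- nri_e - ne_up_minus_down
  denom <- sqrt((ev["up"] + ev["down"]) / ev["n"]^2 +
                (ne["up"] + ne["down"]) / ne["n"]^2)
  z <- if (denom == 0) 0 else total / denom
  list(nri_events = unname(nri_e),
       nonevents_up_minus_down = unname(ne_up_minus_down),
       nri_nonevents = unname(-ne_up_minus_down),
       total_nri = unname(total),
       z = unname(z),
       p = unname(if (denom == 0) 1 else 2 * stats::pnorm(-abs(z))),
       up_events = unname(ev["up"]), down_events = unname(ev["down"]),
       n_events = unname(ev["n"]),
       up_nonevents = unname(ne["up"]), down_nonevents = unname(ne["down"]),
       n_nonevents = unname(ne["n"]))
}

#' Integrated discrimination improvement
#'
#' `IDI = (mean(p_new - p_old) | events) - (mean(p_new - p_old) | non-events)`:
#' the new model's gain in average sensitivity minus its loss in average
#' specificity. The z test uses the paired-difference standard errors in
#' each outcome stratum (Pencina).
#'
#' @param p_old,p_new aligned predicted probabilities from the old and
#'   new model.
#' @param outcome binary outcome (1 = event).
#' @return List with `idi`, `z`, `p` and the two stratum means.
#' @export
idi <- function(p_old, p_new, outcome) {
  if (length(p_old) != length(p_new) || length(p_old) != length(outcome))
    stop("p_old, p_new and outcome must have equal length")
  stopifnot(all(outcome %in% c(0, 1)))
  d <- p_new - p_old
  de <- d[outcome == 1]; dn <- d[outcome == 0]
  if (!length(de) || !length(dn))
    stop("need at least one event and one non-event")
  idi_val <- mean(de) - mean(dn)
  v <- function(x) if (length(x) > 1) stats::var(x) else 0
  se <- sqrt(v(de) / length(de) + v(dn) / length(dn))
  z <- if (se == 0) 0 else idi_val / se
  list(idi = idi_val,
       mean_diff_events = mean(de), mean_diff_nonevents = mean(dn),
       z = z, p = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Full reclassification comparison of two risk models
#'
#' Categorizes both models' predicted probabilities, tabulates movement
#' by outcome, and computes the categorical NRI and the IDI with their
#' tests. Individuals with a missing probability in either model are
#' excluded listwise (count reported).
#'
#' @param p_old,p_new aligned predicted probabilities.
#' @param outcome binary outcome (1 = event).
#' @param cutpoints risk-category cutpoints, default `c(0.20, 0.50)`.
#' @return An object of class `reclassification_result`: list with
#'   `tables`, `nri`, `idi`, `cutpoints`, `n_excluded`.
#' @export
reclassification_compare <- function(p_old, p_new, outcome,
                                     cutpoints = c(0.20, 0.50)) {
  ok <- !is.na(p_old) & !is.na(p_new) & !is.na(outcome)
  old_lab <- risk_categories(p_old[ok], cutpoints)
  new_lab <- risk_categories(p_new[ok], cutpoints)
  tables <- reclassification_tables(old_lab, new_lab, outcome[ok])
  structure(list(tables = tables,
                 nri = categorical_nri(tables),
                 idi = idi(p_old[ok], p_new[ok], outcome[ok]),
                 cutpoints = cutpoints,
                 n_excluded = sum(!ok)),
            class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat("Risk reclassification (new vs old model)\n")
  cat(sprintf("  events:     up %d, down %d of %d -> NRI component %.4f\n",
              x$nri$up_events, x$nri$down_events, x$nri$n_events,
              x$nri$nri_events))
  cat(sprintf("  non-events: up %d, down %d of %d -> up-down %.4f\n",
              x$nri$up_nonevents, x$nri$down_nonevents, x$nri$n_nonevents,
              x$nri$nonevents_up_minus_down))
  cat(sprintf("  total NRI %.4f (p = %.4f); IDI %.4f (p = %.3g)\n",
              x$nri$total_nri, x$nri$p, x$idi$idi, x$idi$p))
  invisible(x)
}
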
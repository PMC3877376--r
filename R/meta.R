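# All pooling is done on the log-OR scale; z is the exact 97.5% normal
# quantile so CIs round-trip with the printed OR (95% CI) presentation.
Z975 <- 1.959964

#' Convert a printed OR (95% CI) entry to a log-OR and standard error
#'
#' Inverts the usual `OR (low-high)` presentation of a Wald interval:
#' `log_or = ln(OR)` and `se = (ln(high) - ln(low)) / (2 * 1.959964)`.
#'
#' @param or_point odds-ratio point estimate (> 0).
#' @param ci_low,ci_high 95% CI bounds on the OR scale, `0 < low <= or_point <= high`.
#' @return A list with `log_or` and `se`.
#' @export
#' @examples
#' or_ci_to_effect(2, 1, 4) # log_or = log(2), se ~ 0.3536
or_ci_to_effect <- function(or_point, ci_low, ci_high) {
  if (any(c(or_point, ci_low, ci_high) <= 0))
    stop("OR and CI bounds must be positive")
  if (ci_low > or_point || or_point > ci_high)
    stop("CI bounds must bracket the point estimate")
  se <- (log(ci_high) - log(ci_low)) / (2 * Z975)
  if (se == 0)
    warning("degenerate CI: standard error is zero")
  list(log_or = log(or_point), se = se)
}

check_effects <- function(log_or, se, min_k = 2L) {
  stopifnot(length(log_or) == length(se))
  if (length(log_or) < min_k)
    stop("need at least ", min_k, " studies")
  if (any(!is.finite(log_or)) || any(!is.finite(se)))
    stop("effects and standard errors must be finite")
  if (any(se <= 0))
    stop("all standard errors must be positive")
}

#' Cochran Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' study effects from the fixed-effect mean; under homogeneity it is
#' chi-squared with k - 1 degrees of freedom.
#'
#' @param log_or per-study effects on the log scale.
#' @param se per-study standard errors (all > 0).
#' @return A list with `Q`, `df` and `p`.
#' @export
cochran_q <- function(log_or, se) {
  check_effects(log_or, se)
  w <- 1 / se^2
  fe <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - fe)^2)
  df <- length(log_or) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity index
#'
#' Percentage of total variation across studies attributable to
#' between-study heterogeneity: `100 * max(0, (Q - df) / Q)`.
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return Percentage in \[0, 100\].
#' @export
i_squared <- function(Q, df) {
  stopifnot(df >= 1, Q >= 0)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-study log odds ratios with inverse-variance weights under a
#' random-effects model. The between-study variance tau^2 is the
#' DerSimonian-Laird moment estimate
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`; random-effects weights are `1/(se^2 + tau2)`.
#' When tau^2 = 0 the result coincides with the fixed-effect
#' inverse-variance pool. A single study is returned unchanged with
#' `Q = 0`, `df = 0`.
#'
#' @param log_or per-study effects on the log scale.
#' @param se per-study standard errors (all > 0).
#' @param labels optional study labels.
#' @return An object of class `meta_result`: a list with `pooled_log_or`,
#'   `pooled_se`, `pooled_or`, `ci95` (OR scale), `p`, `Q`, `df`, `p_Q`,
#'   `i2`, `tau2`, `weights` (random-effects, normalized to sum to 1) and
#'   `k`.
#' @export
#' @examples
#' eff <- Map(or_ci_to_effect,
#'            c(1.54, 1.62, 1.28), c(1.29, 1.28, 0.90), c(1.84, 2.05, 1.82))
#' dersimonian_laird(sapply(eff, `[[`, "log_or"), sapply(eff, `[[`, "se"))
dersimonian_laird <- function(log_or, se, labels = NULL) {
  check_effects(log_or, se, min_k = 1L)
  k <- length(log_or)
  if (k == 1L) {
    Q <- 0; df <- 0L; p_Q <- 1; tau2 <- 0; i2 <- 0
    w_star <- 1 / se^2
  } else {
    het <- cochran_q(log_or, se)
    Q <- het$Q; df <- het$df; p_Q <- het$p
    w <- 1 / se^2
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    i2 <- i_squared(Q, df)
    w_star <- 1 / (se^2 + tau2)
  }
  pooled <- sum(w_star * log_or) / sum(w_star)
  pooled_se <- sqrt(1 / sum(w_star))
  z <- pooled / pooled_se
  out <- list(
    pooled_log_or = pooled,
    pooled_se = pooled_se,
    pooled_or = exp(pooled),
    ci95 = exp(pooled + c(-1, 1) * Z975 * pooled_se),
    p = 2 * stats::pnorm(-abs(z)),
    Q = Q, df = df, p_Q = p_Q, i2 = i2, tau2 = tau2,
    weights = stats::setNames(w_star / sum(w_star), labels),
    k = k
  )
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects (DerSimonian-Laird) pooled OR over %d studies\n", x$k))
  cat(sprintf("  OR %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
              x$pooled_or, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  Q = %.4f (df = %d, p = %.4f), I2 = %.2f%%, tau2 = %.5f\n",
              x$Q, x$df, x$p_Q, x$i2, x$tau2))
  invisible(x)
}

#' Pool printed per-study OR (95% CI) rows
#'
#' Convenience wrapper: converts each `OR (low-high)` row to a log-OR and
#' SE with [or_ci_to_effect()] and pools with [dersimonian_laird()].
#'
#' @param or,ci_low,ci_high per-study OR and 95% CI bounds.
#' @param labels optional study labels.
#' @return A `meta_result`.
#' @export
pool_or_rows <- function(or, ci_low, ci_high, labels = NULL) {
  eff <- Map(or_ci_to_effect, or, ci_low, ci_high)
  dersimonian_laird(vapply(eff, `[[`, numeric(1), "log_or"),
                    vapply(eff, `[[`, numeric(1), "se"),
                    labels = labels)
}

#' Meta-analyze EffectEstimate rows from the association module
#'
#' @param estimates a data.frame of effect estimates as produced by
#'   [fit_logistic()] and friends (columns `log_or`, `se`, `label`).
#' @return A `meta_result`.
#' @export
meta_from_estimates <- function(estimates) {
  stopifnot(all(c("log_or", "se") %in% names(estimates)))
  dersimonian_laird(estimates$log_or, estimates$se, labels = estimates$label)
}
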
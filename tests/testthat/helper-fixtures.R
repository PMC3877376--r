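# Small fixtures shared across tests; everything is built in code.

tiny_panel <- function(k = 3, weight = log(c(1.3, 1.1, 1.5))[seq_len(k)],
                       freq = c(0.3, 0.45, 0.2)[seq_len(k)]) {
  snp_panel(paste0("rs", seq_len(k)), rep(c("A", "G", "T"), length.out = k),
            weight, freq)
}

one_snp_panel <- function(freq = 0.225, weight = log(1.43)) {
  snp_panel("rs12913832", "G", weight, freq)
}

# brute-force AUC by exhaustive pairwise comparison (ties half-credited)
pairwise_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# coarse-to-fine grid search maximiser of the single-predictor logistic
# log-likelihood; independent of glm's IRLS path
grid_logistic <- function(y, x, rounds = 6) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  r0 <- c(-4, 4); r1 <- c(-3, 3)
  for (r in seq_len(rounds)) {
    g0 <- seq(r0[1], r0[2], length.out = 41)
    g1 <- seq(r1[1], r1[2], length.out = 41)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    s0 <- diff(r0) / 40; s1 <- diff(r1) / 40
    r0 <- g0[best[1]] + c(-1, 1) * s0
    r1 <- g1[best[2]] + c(-1, 1) * s1
  }
  c(b0 = mean(r0), b1 = mean(r1))
}

# expand a 2x2 exposure table into individual-level outcome/predictor rows
expand_2x2 <- function(exp_case, exp_ctrl, unexp_case, unexp_ctrl) {
  data.frame(
    y = rep(c(1, 0, 1, 0), c(exp_case, exp_ctrl, unexp_case, unexp_ctrl)),
    x = rep(c(1, 1, 0, 0), c(exp_case, exp_ctrl, unexp_case, unexp_ctrl)))
}
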
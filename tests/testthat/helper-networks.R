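# Small fixture networks and shared test statistics, built in code.

birth_death_network <- function(b, d, x0 = 0L) {
  reaction_network(
    species = list(species("X", x0)),
    reactions = list(
      reaction("birth", b, c(X = 1)),
      reaction("death", d, c(X = -1))
    )
  )
}

# Two-sample chi-square test on pooled-quantile bins; used for
# distributional-equality checks on integer-valued endpoint samples.
two_sample_count_test <- function(x, y, n_bins = 8) {
  pooled <- c(x, y)
  qs <- unique(quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1)))
  brk <- unique(c(-Inf, qs[-c(1, length(qs))], Inf))
  tab <- rbind(table(cut(x, brk)), table(cut(y, brk)))
  keep <- colSums(tab) > 0
  suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))$p.value
}

# Closed-form total-least-squares slope (independent of the eigen route
# used by orthogonal_fit()).
tls_slope_closed_form <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}
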
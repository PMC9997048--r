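# Independent oracles used across the suite.

# Exhaustive best-subset least squares: minimum RSS over all supports of
# size <= K among the penalized coordinates, with `exclude` always in the
# model. Brute force; only for small p.
best_subset_rss <- function(X, y, K, exclude = NULL) {
  p <- ncol(X)
  cand <- setdiff(seq_len(p), exclude)
  rss_of <- function(idx) {
    if (length(idx) == 0L) return(sum(y^2))
    fit <- lm.fit(X[, idx, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  best <- rss_of(exclude)
  for (k in seq_len(min(K, length(cand)))) {
    combs <- combn(cand, k)
    for (j in seq_len(ncol(combs))) {
      best <- min(best, rss_of(c(exclude, combs[, j])))
    }
  }
  best
}

# Numerical-integration oracle for a noise CDF: P(e <= x) by quadrature of
# the density, independent of the closed forms in the package.
noise_cdf_quadrature <- function(noise, x) {
  vapply(x, function(xi) {
    stats::integrate(function(t) noise_density(noise, t), -Inf, xi,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

# Two-sided KS distance of a sample from a CDF function.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}
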
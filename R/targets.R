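#' Target distributions for perturbation
#'
#' A target distribution is the law `R` that every perturbed copy must follow.
#' It bundles a CDF `R(x)` and the generalized inverse quantile
#' `R^-1(u) = inf{x : R(x) >= u}`, the convention that keeps the inverse-CDF
#' transform valid for discrete and mixed targets.
#'
#' @param cdf vectorized function mapping values to `[0, 1]`, nondecreasing
#'   and right-continuous.
#' @param quantile vectorized generalized inverse of `cdf`.
#' @param support one of `"continuous"`, `"discrete"`, `"mixed"`.
#' @param label short description used in provenance records.
#' @return An object of class `flush_target`.
#' @export
new_target_distribution <- function(cdf, quantile,
                                    support = c("continuous", "discrete", "mixed"),
                                    label = "custom") {
  stopifnot(is.function(cdf), is.function(quantile))
  support <- match.arg(support)
  structure(list(cdf = cdf, quantile = quantile, support = support,
                 label = label),
            class = "flush_target")
}

#' @param target a `flush_target`.
#' @param x,u evaluation points / probabilities.
#' @rdname new_target_distribution
#' @export
target_cdf <- function(target, x) target$cdf(x)

#' @rdname new_target_distribution
#' @export
target_quantile <- function(target, u) target$quantile(u)

#' Common parametric targets
#'
#' Convenience constructors for normal, exponential and uniform targets.
#' `target_normal(mean, sd)` is the model-based target used when perturbing a
#' sample to follow an estimated normal law (e.g. `N(Ybar, S^2)` in the
#' normal-mean pivotal example, or `N(0, sigma2)` for regression residuals).
#'
#' @param mean,sd,rate,min,max distribution parameters.
#' @return A `flush_target`.
#' @export
target_normal <- function(mean = 0, sd = 1) {
  check_scalar(sd, "sd", positive = TRUE)
  new_target_distribution(
    cdf = function(x) pnorm(x, mean, sd),
    quantile = function(u) qnorm(u, mean, sd),
    support = "continuous",
    label = sprintf("normal(%g, %g)", mean, sd)
  )
}

#' @rdname target_normal
#' @export
target_exponential <- function(rate = 1) {
  check_scalar(rate, "rate", positive = TRUE)
  new_target_distribution(
    cdf = function(x) pexp(x, rate),
    quantile = function(u) stats::qexp(u, rate),
    support = "continuous",
    label = sprintf("exponential(%g)", rate)
  )
}

#' @rdname target_normal
#' @export
target_uniform <- function(min = 0, max = 1) {
  if (max <= min) stop_df("`max` must exceed `min`")
  new_target_distribution(
    cdf = function(x) pmin(1, pmax(0, (x - min) / (max - min))),
    quantile = function(u) min + u * (max - min),
    support = "continuous",
    label = sprintf("uniform(%g, %g)", min, max)
  )
}

#' Smoothed empirical CDF target
#'
#' Builds a continuous, strictly increasing CDF that agrees exactly with the
#' (optionally weighted) empirical CDF at every jump value, so that the
#' inverse-CDF perturbation transform applies to discrete, mixed and
#' empirical data. Consecutive jump points `(x_(j), c_j)` are joined by
#' piecewise-linear interpolation; below the smallest jump value the CDF
#' descends linearly to zero over half the first inter-jump gap.
#'
#' @param values numeric sample with at least two distinct values.
#' @param weights optional nonnegative weights (e.g. survey weights), same
#'   length as `values`, summing to a positive number.
#' @return A `flush_target` of class `flush_smoothed_ecdf` carrying the jump
#'   points (`$jumps`) and cumulative masses (`$cum`).
#' @examples
#' r <- fit_smoothed_cdf(c(1, 2, 3))
#' target_cdf(r, c(1, 2, 3)) # 1/3, 2/3, 1 exactly
#' @export
fit_smoothed_cdf <- function(values, weights = NULL) {
  if (anyNA(values)) stop_df("`values` must not contain missing values")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0) ||
      sum(weights) <= 0)
    stop_df("`weights` must be nonnegative, match `values`, and have positive sum")
  ord <- order(values)
  x <- values[ord]; w <- weights[ord]
  jumps <- unique(x)
  if (length(jumps) < 2L)
    stop_df("degenerate sample: need at least 2 distinct values to smooth")
  mass <- vapply(split(w, match(x, jumps)), sum, numeric(1))
  keep <- mass > 0
  jumps <- jumps[keep]; mass <- mass[keep]
  if (length(jumps) < 2L)
    stop_df("degenerate sample: need at least 2 distinct values with positive weight")
  cum <- cumsum(mass) / sum(mass)
  cum[length(cum)] <- 1
  x0 <- jumps[1L] - (jumps[2L] - jumps[1L]) / 2
  kx <- c(x0, jumps); kp <- c(0, cum)
  obj <- new_target_distribution(
    cdf = function(x) approx(kx, kp, xout = x, rule = 2, ties = "ordered")$y,
    quantile = function(u) {
      if (any(u < 0 | u > 1, na.rm = TRUE))
        stop_df("probabilities must lie in [0, 1]")
      approx(kp, kx, xout = u, rule = 2, ties = "ordered")$y
    },
    support = if (length(jumps) == length(values)) "continuous" else "mixed",
    label = sprintf("smoothed ecdf (%d jumps)", length(jumps))
  )
  obj$jumps <- jumps
  obj$cum <- cum
  class(obj) <- c("flush_smoothed_ecdf", class(obj))
  obj
}

# Smoothed target over integer category codes 1..k with class probabilities
# `probs`; used for binary/nominal components of the conditional chain.
smoothed_discrete_target <- function(probs, codes = seq_along(probs)) {
  stopifnot(length(probs) >= 2L, all(probs >= 0), abs(sum(probs) - 1) < 1e-8)
  rep_counts <- pmax(probs, 0)
  fit_smoothed_cdf(codes, weights = rep_counts + 1e-12)
}

#' @export
print.flush_target <- function(x, ...) {
  cat(sprintf("<target distribution: %s, support %s>\n", x$label, x$support))
  invisible(x)
}
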
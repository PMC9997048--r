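#' Specify a pivotal quantity for Monte-Carlo inference
#'
#' A pivotal specification bundles three pure functions: an estimator mapping
#' a sample to a point estimate and its standard error; a pivotal
#' `T(estimate, theta)` whose law does not depend on the unknown parameter
#' and which is invertible in `theta` for interval construction; and a target
#' builder mapping the estimate to the plug-in target distribution
#' `R = F(theta) |_{theta = theta_hat}` from which perturbed samples are
#' drawn.
#'
#' @param estimate function(sample) returning `list(theta =, se =)`.
#' @param pivotal function(estimate_list, theta) returning a scalar; for the
#'   location-scale pivotals used here, `T(a, a) = 0`.
#' @param target function(estimate_list, sample) returning a `flush_target`.
#' @param label short description.
#' @return An object of class `flush_pivotal_spec`.
#' @export
pivotal_spec <- function(estimate, pivotal, target, label = "custom") {
  stopifnot(is.function(estimate), is.function(pivotal), is.function(target))
  structure(list(estimate = estimate, pivotal = pivotal, target = target,
                 label = label),
            class = "flush_pivotal_spec")
}

#' The studentized normal-mean pivotal
#'
#' `T = (Ybar - theta) / (S / sqrt(n))`, with plug-in target `N(Ybar, S^2)`.
#' Conditionally on the raw sample, the perturbed pivotal is exactly
#' t-distributed on `n - 1` degrees of freedom, which is what makes the
#' Monte-Carlo interval exact for any sample size.
#'
#' @return A `flush_pivotal_spec`.
#' @export
normal_mean_spec <- function() {
  pivotal_spec(
    estimate = function(z) list(theta = mean(z), se = sd(z) / sqrt(length(z))),
    pivotal = function(est, theta) (est$theta - theta) / est$se,
    target = function(est, z) target_normal(mean(z), sd(z)),
    label = "normal mean (studentized)"
  )
}

#' Monte-Carlo simulation of a perturbed pivotal
#'
#' Step 1 of the Monte-Carlo inference procedure: generates `D` independent
#' perturbed samples, each following the plug-in target, applies the same
#' estimator to each, and returns the perturbed pivotal draws
#' `T*_d = T(theta_hat(Z*_d), theta_hat)` together with the perturbed
#' estimates. Draws on which the estimator fails are dropped and replaced,
#' with the failure count reported.
#'
#' @param sample numeric raw sample.
#' @param spec a `flush_pivotal_spec`.
#' @param D Monte-Carlo size (`>= 2`).
#' @param plan a `flush_plan`; its `m` is ignored (the procedure needs `D`
#'   independent copies, drawn with fresh rank couplings).
#' @return A list with `theta_hat` (estimate on the raw sample), `t_star`,
#'   `theta_star` (length-`D` vectors) and `n_failed`.
#' @export
monte_carlo_pivotal <- function(sample, spec, D, plan) {
  if (!inherits(spec, "flush_pivotal_spec"))
    stop_df("`spec` must be a flush_pivotal_spec")
  check_scalar(D, "D"); if (D < 2) stop_df("`D` must be at least 2")
  D <- as.integer(D)
  est <- spec$estimate(sample)
  target <- spec$target(est, sample)

  t_star <- theta_star <- numeric(0)
  n_failed <- 0L
  round <- 0L
  need <- D
  while (need > 0L && round < 50L) {
    plan_d <- perturbation_plan(plan$noise, m = need,
                                seed = derive_seed(plan$seed %||% 0,
                                                   paste0("mc", round)),
                                dp_mode = plan$dp_mode, epsilon = plan$epsilon)
    if (is.null(plan$seed)) plan_d$seed <- NULL
    Zs <- perturb_univariate(sample, target, plan_d, coupling = "fresh")$values
    for (d in seq_len(ncol(Zs))) {
      ed <- tryCatch(spec$estimate(Zs[, d]), error = function(e) NULL)
      td <- if (!is.null(ed))
        tryCatch(spec$pivotal(ed, est$theta), error = function(e) NULL)
      if (is.null(ed) || is.null(td) || !is.finite(td)) {
        n_failed <- n_failed + 1L
      } else {
        t_star <- c(t_star, td)
        theta_star <- c(theta_star, ed$theta)
      }
    }
    need <- D - length(t_star)
    round <- round + 1L
  }
  if (need > 0L)
    stop_df("estimator failed on too many perturbed samples (",
            n_failed, " failures)")
  list(theta_hat = est, t_star = t_star[seq_len(D)],
       theta_star = theta_star[seq_len(D)], n_failed = n_failed)
}

#' Bias correction from perturbed estimates
#'
#' Step 2: `B = mean(theta*_d) - theta_hat`, and the corrected estimate is
#' `theta_c = theta_hat + B` (the additive convention; set
#' `sign = "classical"` for the usual `theta_hat - B`).
#'
#' @param theta_hat point estimate on the raw sample.
#' @param theta_star_draws perturbed estimates (at least one).
#' @param sign `"additive"` (default) or `"classical"`.
#' @return A list with `bias` and `theta_c`.
#' @examples
#' bias_correct(2, c(2.5, 2.5)) # bias 0.5, corrected 2.5
#' @export
bias_correct <- function(theta_hat, theta_star_draws,
                         sign = c("additive", "classical")) {
  sign <- match.arg(sign)
  if (length(theta_star_draws) < 1L) stop_df("no perturbed estimates supplied")
  B <- mean(theta_star_draws) - theta_hat
  theta_c <- if (sign == "additive") theta_hat + B else theta_hat - B
  list(bias = B, theta_c = theta_c)
}

#' Invert a studentized pivotal into a confidence interval
#'
#' Step 3: with `T = (theta_hat - theta) / se`, the `alpha/2` and
#' `1 - alpha/2` empirical quantiles `q_lo, q_hi` of the perturbed pivotal
#' draws invert to `[theta_c - q_hi * se, theta_c - q_lo * se]`. Empirical
#' quantiles use the interpolated inverse-empirical-CDF convention
#' (`type = 4`), which is stable for large draw counts. Analytically known
#' quantiles may be supplied directly via `quantiles`.
#'
#' @param theta_c (bias-corrected) point estimate.
#' @param se standard error used by the pivotal (`> 0`).
#' @param t_star_draws perturbed pivotal draws.
#' @param alpha significance level in (0, 1); the interval has level
#'   `1 - alpha`.
#' @param quantiles optional length-2 numeric `(q_lo, q_hi)` overriding the
#'   empirical quantiles.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(theta_c, se, t_star_draws = NULL,
                                alpha = 0.05, quantiles = NULL) {
  check_scalar(se, "se", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_df("`alpha` must lie in (0, 1)")
  if (is.null(quantiles)) {
    if (is.null(t_star_draws)) stop_df("supply `t_star_draws` or `quantiles`")
    if (length(t_star_draws) < ceiling(2 / alpha))
      stop_df("too few pivotal draws for the requested quantiles")
    quantiles <- quantile(t_star_draws, c(alpha / 2, 1 - alpha / 2),
                          type = 4, names = FALSE)
  }
  c(lower = theta_c - quantiles[2L] * se,
    upper = theta_c - quantiles[1L] * se)
}

new_inference_result <- function(theta_hat, se, bias, theta_c, t_star,
                                 theta_star, ci, D, alpha, extra = list()) {
  structure(c(list(theta_hat = theta_hat, se = se, bias = bias,
                   theta_c = theta_c, t_star = t_star,
                   theta_star = theta_star, ci = ci, D = D, alpha = alpha),
              extra),
            class = "flush_inference")
}

#' @export
print.flush_inference <- function(x, ...) {
  cat(sprintf(
    "<Monte-Carlo pivotal inference>\n  estimate %.6g (se %.4g), bias %.4g, corrected %.6g\n  %g%% CI [%.6g, %.6g]  (D = %d draws%s)\n",
    x$theta_hat, x$se, x$bias, x$theta_c, 100 * (1 - x$alpha),
    x$ci[1L], x$ci[2L], x$D,
    if (!is.null(x$n_failed) && x$n_failed > 0)
      sprintf(", %d failed draws replaced", x$n_failed) else ""))
  invisible(x)
}

#' Monte-Carlo confidence interval for a normal mean
#'
#' Runs the full three-step procedure (pivotal simulation, bias correction,
#' quantile inversion) for the population mean of a normal sample, using
#' Laplace(0, 1/epsilon) perturbation noise and the plug-in target
#' `N(Ybar, S^2)`.
#'
#' @param z numeric sample.
#' @param D Monte-Carlo size.
#' @param epsilon noise privacy factor (noise scale `1/epsilon`).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return A `flush_inference` object.
#' @export
flush_mean_ci <- function(z, D = 10000L, epsilon = 0.01, alpha = 0.05,
                          seed = NULL) {
  plan <- perturbation_plan(make_noise_model("laplace", 1 / epsilon),
                            m = 1L, seed = seed)
  mc <- monte_carlo_pivotal(z, normal_mean_spec(), D, plan)
  bc <- bias_correct(mc$theta_hat$theta, mc$theta_star)
  ci <- confidence_interval(bc$theta_c, mc$theta_hat$se, mc$t_star, alpha)
  new_inference_result(mc$theta_hat$theta, mc$theta_hat$se, bc$bias,
                       bc$theta_c, mc$t_star, mc$theta_star, ci,
                       D = length(mc$t_star), alpha = alpha,
                       extra = list(n_failed = mc$n_failed))
}
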
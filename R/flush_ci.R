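#' Monte-Carlo confidence interval for one regression coefficient
#'
#' Constructs a confidence interval for coefficient `l` in a (possibly
#' high-dimensional) linear model via perturbed copies of the response. The
#' mean function and error variance are estimated on a holdout sample
#' independent of the inference sample; each of the `D` perturbed copies
#' releases `Y*_id = mu_hat(X_i) + eps*_id` where the residual perturbation
#' follows `N(0, sigma2_hat)` through the rank-coupled uniform-noise map with
#' Laplace(0, 1/epsilon) noise. The truncated-L1 constrained regression
#' (coordinate `l` unpenalized) is refit on every copy, warm-started from the
#' raw fit's support, and the three inference steps (pivotal simulation with
#' `T* = (beta*_l - beta_hat_l) / SE*`, bias correction, quantile inversion)
#' yield the interval.
#'
#' @param X `n x p` design matrix of the inference sample.
#' @param y responses of the inference sample.
#' @param l coordinate (1-based) whose coefficient is of interest.
#' @param D Monte-Carlo size (`>= 100`).
#' @param epsilon noise privacy factor; the Laplace noise scale is
#'   `1/epsilon`.
#' @param alpha significance level.
#' @param holdout optional `list(X =, y =)` holdout sample; when omitted,
#'   `holdout_fraction` of the rows of `(X, y)` are split off (seeded) for
#'   the holdout role.
#' @param holdout_fraction fraction used when `holdout` is not supplied.
#' @param K constraint size; chosen by 5-fold cross-validation on the holdout
#'   when `NULL`.
#' @param tau truncation threshold (see [tlp_regression()]).
#' @param seed integer root seed.
#' @return A `flush_inference` object with extra fields `K`, `tau`,
#'   `sigma2_holdout` and `n_failed`.
#' @export
flush_ci_for_regression <- function(X, y, l, D = 1000L, epsilon = 0.01,
                                    alpha = 0.05, holdout = NULL,
                                    holdout_fraction = 0.5, K = NULL,
                                    tau = NULL, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  check_scalar(D, "D"); if (D < 100) stop_df("`D` must be at least 100")
  D <- as.integer(D)
  check_scalar(l, "l"); if (l < 1 || l > p) stop_df("`l` out of range")

  if (is.null(holdout)) {
    n_h <- round(n * holdout_fraction)
    if (n_h < 4L || n - n_h < 4L) stop_df("too few rows to split a holdout")
    idx <- with_seed(derive_seed(seed, "split"), sample.int(n, n_h))
    holdout <- list(X = X[idx, , drop = FALSE], y = y[idx])
    X <- X[-idx, , drop = FALSE]; y <- y[-idx]
    n <- nrow(X)
  }
  tau <- tau %||% (0.01 * sqrt(log(p) / n))
  if (is.null(K))
    K <- cv_choose_K(holdout$X, holdout$y, exclude = l, tau = tau,
                     seed = derive_seed(seed, "cv"))

  # holdout fit: mean function and error variance for residual perturbation
  fit_h <- tlp_regression(holdout$X, holdout$y, K = K, tau = tau, exclude = l)
  mu <- drop(X %*% fit_h$beta)
  sigma2_h <- fit_h$sigma2
  if (!is.finite(sigma2_h) || sigma2_h <= 0)
    stop_df("holdout residual variance is degenerate")

  # raw fit on the inference sample
  fit0 <- tlp_regression(X, y, K = K, tau = tau, exclude = l)
  theta_hat <- fit0$beta[l]
  se0 <- fit0$se_excluded
  if (!is.finite(se0) || se0 <= 0)
    stop_df("standard error of the raw fit is degenerate")

  plan <- perturbation_plan(make_noise_model("laplace", 1 / epsilon), m = D,
                            seed = derive_seed(seed, "residual-perturb"))
  Ystar <- perturb_residuals(y, mu, sigma2_h, plan, coupling = "fresh")$values

  G <- crossprod(X)
  warm <- list(fit0$active)
  theta_star <- se_star <- rep(NA_real_, D)
  for (d in seq_len(D)) {
    yd <- Ystar[, d]
    fd <- tryCatch(
      tlp_regression_gram(G, drop(crossprod(X, yd)), sum(yd^2), n, K, tau,
                          exclude = l, starts = warm),
      error = function(e) NULL)
    if (!is.null(fd) && is.finite(fd$se_excluded) && fd$se_excluded > 0) {
      theta_star[d] <- fd$beta[l]
      se_star[d] <- fd$se_excluded
    }
  }
  ok <- is.finite(theta_star)
  n_failed <- sum(!ok)
  if (sum(ok) < max(100L, ceiling(2 / alpha)))
    stop_df("too many failed refits on perturbed copies (", n_failed, ")")
  theta_star <- theta_star[ok]; se_star <- se_star[ok]

  t_star <- (theta_star - theta_hat) / se_star
  bc <- bias_correct(theta_hat, theta_star)
  ci <- confidence_interval(bc$theta_c, se0, t_star, alpha)
  new_inference_result(theta_hat, se0, bc$bias, bc$theta_c, t_star,
                       theta_star, ci, D = length(t_star), alpha = alpha,
                       extra = list(K = K, tau = tau,
                                    sigma2_holdout = sigma2_h,
                                    coefficient = l, n_failed = n_failed))
}
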
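#' Perturbation plan
#'
#' Bundles the knobs of a perturbation run: the noise model, the number of
#' perturbed copies `m`, the RNG seed, and the differential-privacy mode. In
#' dp mode the noise family must be Laplace and an overall privacy factor
#' `epsilon` must be given; smaller `epsilon` means stronger privacy and a
#' larger noise scale.
#'
#' @param noise a `flush_noise` object.
#' @param m number of perturbed copies per record (`>= 1`).
#' @param seed optional integer root seed.
#' @param dp_mode logical; enable the epsilon-differential-privacy discipline.
#' @param epsilon overall privacy factor, required when `dp_mode`.
#' @param keep_noise logical; retain all noise draws in the output for audit
#'   (defaults to `dp_mode`, where the noise stream is part of the ledger).
#' @return An object of class `flush_plan`.
#' @export
perturbation_plan <- function(noise, m = 1L, seed = NULL, dp_mode = FALSE,
                              epsilon = NULL, keep_noise = dp_mode) {
  if (!inherits(noise, "flush_noise")) stop_df("`noise` must be a flush_noise")
  check_scalar(m, "m"); if (m < 1) stop_df("`m` must be at least 1")
  if (dp_mode) {
    if (is.null(epsilon)) stop_df("`epsilon` is required in dp_mode")
    check_scalar(epsilon, "epsilon", positive = TRUE)
    if (noise$family != "laplace")
      stop_df("dp_mode requires laplace noise")
  }
  structure(list(noise = noise, m = as.integer(m), seed = seed,
                 dp_mode = isTRUE(dp_mode), epsilon = epsilon,
                 keep_noise = isTRUE(keep_noise)),
            class = "flush_plan")
}

new_perturbed <- function(values, ids, plan, target_label, noise_log = NULL,
                          kind = "univariate", budget = NULL) {
  structure(list(values = values, ids = ids, plan = plan,
                 target = target_label, noise_log = noise_log,
                 kind = kind, budget = budget),
            class = "flush_perturbed")
}

#' @export
print.flush_perturbed <- function(x, ...) {
  m <- if (x$kind == "multivariate") length(x$values) else ncol(x$values)
  cat(sprintf("<perturbed data: %s, n = %d, m = %d copies, target %s>\n",
              x$kind, length(x$ids), m, x$target))
  invisible(x)
}

#' Perturb a univariate sample to follow a target distribution
#'
#' Implements the core nonlinear perturbation: rank-matched uniforms `U_i`
#' receive independent noise `e_ij` and are mapped through
#' `H = R^-1(G(.))`, where `G` is the CDF of `U + e` and `R` the target, so
#' each perturbed value `Z*_ij = H(U_i + e_ij)` follows `R` exactly while the
#' record identifier survives through the ranks.
#'
#' With `coupling = "shared"` one uniform sample is drawn and reused across
#' the `m` copies, making copies of the same record conditionally independent
#' given `U_i`. With `coupling = "fresh"` every copy gets its own
#' independently rank-matched uniforms, making the `m` copies fully
#' independent perturbed samples — the form needed by the Monte-Carlo
#' pivotal-inference step.
#'
#' @param z numeric raw sample.
#' @param target a `flush_target`.
#' @param plan a `flush_plan`.
#' @param coupling `"shared"` (default) or `"fresh"`; see Details.
#' @return A `flush_perturbed` object whose `$values` is an `n x m` matrix.
#' @examples
#' plan <- perturbation_plan(make_noise_model("laplace", 0.1), m = 2, seed = 1)
#' perturb_univariate(rnorm(5), target_normal(0, 1), plan)
#' @export
perturb_univariate <- function(z, target, plan,
                               coupling = c("shared", "fresh")) {
  coupling <- match.arg(coupling)
  if (!inherits(target, "flush_target")) stop_df("`target` must be a flush_target")
  if (!inherits(plan, "flush_plan")) stop_df("`plan` must be a flush_plan")
  n <- length(z); m <- plan$m
  if (n < 1L) stop_df("`z` must be non-empty")
  g <- convolve_uniform_noise(plan$noise)
  with_seed(plan$seed, {
    U <- if (coupling == "shared") {
      matrix(rank_matched_uniforms(z)$u, n, m)
    } else {
      rank_matched_uniform_matrix(z, m)
    }
    E <- matrix(noise_sample(plan$noise, n * m), n, m)
    V <- convolved_cdf(g, U + E)
    V <- pmin(1 - 1e-12, pmax(1e-12, V))
    Zs <- matrix(target_quantile(target, V), n, m)
    new_perturbed(Zs, ids = names(z) %||% seq_len(n), plan = plan,
                  target_label = target$label,
                  noise_log = if (plan$keep_noise) as.vector(E))
  })
}

#' Perturb regression responses through their residuals
#'
#' Releases `Y*_ij = mu_i + eps*_ij` where `mu_i` are fitted means, and
#' `eps*_ij` is a univariate perturbation of the raw residuals `y - mu` with
#' target `N(0, sigma2_hat)`. In dp mode the fitted means and variance must
#' come from a holdout sample independent of `y`.
#'
#' @param y numeric responses.
#' @param fitted_means fitted values `mu(X_i)`, same length as `y`.
#' @param sigma2_hat positive residual variance estimate.
#' @param plan a `flush_plan`.
#' @param coupling passed to [perturb_univariate()].
#' @return A `flush_perturbed` with `$values` an `n x m` matrix of perturbed
#'   responses.
#' @export
perturb_residuals <- function(y, fitted_means, sigma2_hat, plan,
                              coupling = c("shared", "fresh")) {
  coupling <- match.arg(coupling)
  if (length(fitted_means) != length(y))
    stop_df("`fitted_means` must match `y` in length")
  check_scalar(sigma2_hat, "sigma2_hat", positive = TRUE)
  r <- y - fitted_means
  pu <- perturb_univariate(r, target_normal(0, sqrt(sigma2_hat)), plan,
                           coupling = coupling)
  pu$values <- pu$values + fitted_means
  pu$target <- sprintf("residual normal(0, %g) about fitted means", sigma2_hat)
  pu
}
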
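#' Construct a noise model for data perturbation
#'
#' The perturbation scheme adds continuous, zero-centred noise `e` to
#' rank-coupled uniforms before mapping through the target quantile function.
#' Three symmetric families are supported. For `"laplace"` the scale is the
#' usual Laplace scale `b` of Laplace(0, b) (used at `b = p/epsilon` in the
#' differential-privacy mode); for `"gaussian"` the scale is the standard
#' deviation; for `"uniform"` the noise is Uniform[-scale, scale].
#'
#' @param family one of `"laplace"`, `"gaussian"`, `"uniform"`.
#' @param scale positive scale parameter.
#' @return An object of class `flush_noise` with mutually consistent CDF,
#'   density, quantile and sampling functions (see [noise_cdf()]).
#' @examples
#' nm <- make_noise_model("laplace", 1)
#' noise_cdf(nm, 0) # 0.5 by symmetry
#' @export
make_noise_model <- function(family = c("laplace", "gaussian", "uniform"),
                             scale) {
  family <- match.arg(family)
  check_scalar(scale, "scale", positive = TRUE)
  structure(list(family = family, scale = scale), class = "flush_noise")
}

#' Distribution functions of a noise model
#'
#' @param noise a `flush_noise` object.
#' @param x,u,n evaluation points, probabilities, or a sample size.
#' @return `noise_cdf`/`noise_density`/`noise_quantile` return numeric vectors
#'   the length of their input; `noise_sample` returns `n` draws.
#' @export
noise_cdf <- function(noise, x) {
  b <- noise$scale
  switch(noise$family,
    laplace  = ifelse(x < 0, 0.5 * exp(x / b), 1 - 0.5 * exp(-x / b)),
    gaussian = pnorm(x, sd = b),
    uniform  = pmin(1, pmax(0, (x + b) / (2 * b)))
  )
}

#' @rdname noise_cdf
#' @export
noise_density <- function(noise, x) {
  b <- noise$scale
  switch(noise$family,
    laplace  = exp(-abs(x) / b) / (2 * b),
    gaussian = dnorm(x, sd = b),
    uniform  = ifelse(abs(x) <= b, 1 / (2 * b), 0)
  )
}

#' @rdname noise_cdf
#' @export
noise_quantile <- function(noise, u) {
  if (any(u < 0 | u > 1, na.rm = TRUE)) stop_df("probabilities must lie in [0, 1]")
  b <- noise$scale
  switch(noise$family,
    laplace  = ifelse(u < 0.5, b * log(2 * u), -b * log(2 * (1 - u))),
    gaussian = qnorm(u, sd = b),
    uniform  = (2 * u - 1) * b
  )
}

#' @rdname noise_cdf
#' @export
noise_sample <- function(noise, n) {
  noise_quantile(noise, runif(n))
}

#' @export
print.flush_noise <- function(x, ...) {
  cat(sprintf("<noise model: %s, scale %g>\n", x$family, x$scale))
  invisible(x)
}
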
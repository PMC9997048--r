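#' @useDynLib dataflush, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef dnorm glm lm pexp plogis pnorm pt qnorm qt
#'   quantile residuals rnorm rpois runif sd predict binomial cor uniroot
#'   rbinom
#' @importFrom utils combn read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named child seed from a root seed
#'
#' All randomness in the package flows from a single root seed through named
#' child streams (coupling, noise, split, ...), so partial reruns of a
#' workflow are reproducible. The derivation is a fixed polynomial hash of the
#' stream label folded into the root seed modulo 2^31 - 2.
#'
#' @param seed integer root seed (may be `NULL`, giving `NULL`).
#' @param label character stream label.
#' @return An integer seed in `[1, 2^31 - 2]`, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483646
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m + h) %% m + 1)
}

# Evaluate `expr` under `seed` (if non-NULL) and restore the caller's RNG
# state afterwards, so library calls do not disturb user simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Content fingerprint of a data set, used by the privatization ledger to
# enforce that the holdout split is fixed once selected.
dataset_hash <- function(data) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(data, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

# Row fingerprints, used to detect holdout violations in dp mode.
row_keys <- function(data) {
  apply(data, 1L, function(r) paste(format(r, trim = TRUE), collapse = "\r"))
}

stop_df <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_df("`", name, "` must be a single finite number")
  if (positive && x <= 0)
    stop_df("`", name, "` must be positive")
  invisible(x)
}
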
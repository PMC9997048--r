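#' Rank-matched uniform coupling
#'
#' Draws an i.i.d. Uniform[0, 1] sample and relabels it so that the rank of
#' `u[i]` equals the rank of `z[i]` in the raw sample. The relabelled sample
#' is still marginally i.i.d. uniform, but carries the raw sample's ranks —
#' this is what preserves the record identifier through perturbation (the
#' Spearman correlation between `z` and its perturbed copy tends to 1 as the
#' noise vanishes). Ties in `z` are broken uniformly at random under the
#' supplied seed, which preserves the uniform marginal and keeps runs
#' reproducible.
#'
#' @param z numeric raw sample (length `n >= 1`).
#' @param seed optional integer seed.
#' @return An object of class `flush_coupling` with elements `u` (the
#'   relabelled uniforms), `rank` (the tie-broken ranks of `z`) and `seed`.
#' @examples
#' rc <- rank_matched_uniforms(c(3, 1, 2), seed = 1)
#' order(rc$u) # 2 3 1: u follows the ranks of z
#' @export
rank_matched_uniforms <- function(z, seed = NULL) {
  n <- length(z)
  if (n < 1L) stop_df("`z` must be non-empty")
  if (anyNA(z)) stop_df("`z` must not contain missing values")
  with_seed(seed, {
    r <- rank(z, ties.method = "random")
    u <- sort(runif(n))[r]
    structure(list(u = u, rank = r, seed = seed), class = "flush_coupling")
  })
}

# n x D matrix of independently rank-matched uniform samples (one coupling
# per column), used when independent perturbed samples are required.
rank_matched_uniform_matrix <- function(z, D) {
  n <- length(z)
  um <- matrix(runif(n * D), n, D)
  um <- apply(um, 2L, sort)
  if (n == 1L) um <- matrix(um, 1L, D)
  if (anyDuplicated(z) == 0L) {
    um[rank(z), , drop = FALSE]
  } else {
    for (j in seq_len(D)) um[, j] <- um[rank(z, ties.method = "random"), j]
    um
  }
}
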
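#' Perturb a mixed-type table through the chain rule
#'
#' Applies the univariate perturbation to each variable in turn: the first
#' variable is perturbed with rank-matched uniforms (one shared uniform
#' sample reused across the `m` copies, so copies of a record are
#' conditionally independent given its uniforms, while the record identifier
#' is preserved); every later variable draws fresh unmatched uniforms and is
#' mapped through the fitted conditional target given the already-perturbed
#' prefix of the same record and copy. Discrete variables are perturbed on
#' their category codes and mapped back to categories via the generalized
#' inverse of the conditional class CDF.
#'
#' In dp mode every component uses Laplace noise at the per-variable budget
#' scale `p / epsilon`, and the chain must have been fitted on rows disjoint
#' from `data` (the holdout discipline); a shared row triggers an error.
#'
#' @param data data frame of raw records to perturb.
#' @param chain a `flush_chain` from [fit_conditional_chain()].
#' @param plan a `flush_plan`.
#' @return A `flush_perturbed` whose `$values` is a list of `m` data frames.
#' @export
perturb_multivariate <- function(data, chain, plan) {
  if (!inherits(chain, "flush_chain")) stop_df("`chain` must be a flush_chain")
  if (!inherits(plan, "flush_plan")) stop_df("`plan` must be a flush_plan")
  vars <- chain$order
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_df("columns missing from data: ", paste(missing_cols, collapse = ", "))
  n <- nrow(data); p <- length(vars); m <- plan$m
  if (n < 1L) stop_df("`data` must have at least one row")
  schema <- chain$schema

  noise <- plan$noise
  budget <- NULL
  if (plan$dp_mode) {
    if (any(row_keys(data[vars]) %in% chain$row_keys))
      stop_df("holdout violation: dp_mode requires the chain to be fitted on ",
              "rows disjoint from the data being perturbed")
    budget <- privacy_budget(plan$epsilon, p)
    noise <- make_noise_model("laplace", budget$scale)
  }
  g <- convolve_uniform_noise(noise)

  z1 <- data[[vars[1L]]]
  ty1 <- schema$types[[vars[1L]]]
  z1_num <- if (is_discrete_type(ty1))
    as.integer(code_column(z1, ty1, chain$levels[[vars[1L]]])) else z1

  with_seed(plan$seed, {
    u1 <- rank_matched_uniforms(z1_num)$u
    copies <- vector("list", m)
    noise_log <- if (plan$keep_noise) numeric(0)
    for (j in seq_len(m)) {
      coded <- list(); out <- list()
      for (l in seq_len(p)) {
        v <- vars[l]; ty <- schema$types[[v]]
        u <- if (l == 1L) u1 else runif(n)
        e <- noise_sample(noise, n)
        if (plan$keep_noise) noise_log <- c(noise_log, e)
        vv <- pmin(1 - 1e-12, pmax(1e-12, convolved_cdf(g, u + e)))
        prefix <- if (l > 1L)
          as.data.frame(coded, optional = TRUE, stringsAsFactors = FALSE)
        zs <- chain_perturb_component(chain, l, prefix, vv)
        if (is_discrete_type(ty)) {
          lev <- chain$levels[[v]]
          coded[[v]] <- factor(lev[zs], levels = lev)
          out[[v]] <- decode_column(zs, ty, lev, chain$templates[[v]])
        } else {
          coded[[v]] <- zs
          out[[v]] <- zs
        }
        if (!is.null(budget)) budget$consumed <- unique(c(budget$consumed, v))
      }
      copies[[j]] <- as.data.frame(out, optional = TRUE,
                                   stringsAsFactors = FALSE)
    }
    new_perturbed(copies, ids = rownames(data) %||% seq_len(n), plan = plan,
                  target_label = sprintf("conditional chain (%d variables)", p),
                  noise_log = noise_log, kind = "multivariate",
                  budget = budget)
  })
}
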
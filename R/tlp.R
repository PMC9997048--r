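#' Truncated-L1 constrained least-squares regression
#'
#' Fits linear regression (no intercept) under the truncated-L1 penalty
#' constraint `sum_j min(|beta_j| / tau, 1) <= K` over the penalized
#' coordinates, a computable surrogate for the L0 constraint
#' `||beta||_0 <= K`. The coordinate `exclude` (the coefficient of interest
#' in the inference procedure) is always in the model and never penalized.
#'
#' At the default small truncation threshold `tau = 0.01 sqrt(log(p) / n)`
#' the constraint is effectively a support-size bound, and the solver runs a
#' steepest-descent support search (single-coordinate additions and swaps,
#' each strictly decreasing the residual sum of squares) warm-started from
#' the lasso solution path and a marginal-correlation screen. The final
#' coefficients are the least-squares refit on the selected support, whose
#' observed information supplies the reported standard error of the excluded
#' coordinate.
#'
#' @param X `n x p` design matrix.
#' @param y numeric response vector of length `n`.
#' @param K constraint size, `1 <= K < p` (number of penalized variables
#'   allowed into the model).
#' @param tau truncation threshold; default `0.01 * sqrt(log(p) / n)`.
#' @param exclude optional coordinate (1-based) kept unpenalized.
#' @param starts optional list of integer vectors (1-based candidate
#'   supports) used as additional warm starts; when supplied the lasso-path
#'   warm start is skipped, which is how refits on perturbed copies reuse the
#'   raw fit's support.
#' @param max_moves cap on greedy moves per start.
#' @return An object of class `flush_tlp`: `beta` (length-`p` coefficient
#'   vector), `active` (selected penalized coordinates), `objective` (residual
#'   sum of squares), `se_excluded`, `sigma2`, `trajectory` (monotone RSS
#'   trajectory of the accepted start), `converged`, and the tuning used.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- 5 * X[, 1]
#' fit <- tlp_regression(X, y, K = 1, exclude = 1)
#' round(fit$beta, 6) # (5, 0, 0)
#' @export
tlp_regression <- function(X, y, K, tau = NULL, exclude = NULL,
                           starts = NULL, max_moves = 200L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_df("`y` must match `nrow(X)`")
  if (n < 2L) stop_df("need at least 2 observations")
  check_scalar(K, "K")
  p_pen <- if (is.null(exclude)) p else p - 1L
  if (K < 1 || K > p_pen) stop_df("`K` must satisfy 1 <= K <= ", p_pen)
  if (!is.null(exclude)) {
    check_scalar(exclude, "exclude")
    if (exclude < 1 || exclude > p) stop_df("`exclude` out of range")
  }
  tau <- tau %||% (0.01 * sqrt(log(p) / n))
  check_scalar(tau, "tau", positive = TRUE)

  G <- crossprod(X)
  cvec <- drop(crossprod(X, y))
  yty <- sum(y^2)
  fit <- tlp_regression_gram(G, cvec, yty, n, K, tau, exclude, X = X, y = y,
                             starts = starts, max_moves = max_moves)
  fit
}

# Candidate supports along the lasso path (coefficient of interest
# unpenalized), each ordered by decreasing coefficient magnitude so that
# truncation to a constraint size keeps the strongest variables. Shared by
# tlp_regression and the cross-validation tuner.
lasso_start_supports <- function(X, y, exclude = NULL, max_starts = 8L) {
  p <- ncol(X)
  pf <- rep(1, p)
  if (!is.null(exclude)) pf[exclude] <- 0
  lp <- tryCatch(
    glmnet::glmnet(X, y, intercept = FALSE, penalty.factor = pf,
                   nlambda = 40, standardize = TRUE),
    error = function(e) NULL)
  if (is.null(lp)) return(list())
  B <- as.matrix(lp$beta)
  out <- list(); seen <- character(0)
  for (k in seq_len(ncol(B))) {
    bj <- B[, k]
    if (!is.null(exclude)) bj[exclude] <- 0
    nz <- which(bj != 0)
    nz <- nz[order(abs(bj[nz]), decreasing = TRUE)]
    key <- paste(sort(nz), collapse = ",")
    if (length(nz) && !(key %in% seen)) {
      seen <- c(seen, key)
      out <- c(out, list(as.integer(nz)))
    }
    if (length(out) >= max_starts) break
  }
  out
}

# Gram-space workhorse shared by tlp_regression and the Monte-Carlo refits.
tlp_regression_gram <- function(G, cvec, yty, n, K, tau, exclude = NULL,
                                X = NULL, y = NULL, starts = NULL,
                                max_moves = 200L) {
  p <- nrow(G)
  l0 <- if (is.null(exclude)) -1L else as.integer(exclude - 1L)

  # the empty start (pure forward selection) is kept for cold fits; fits
  # with explicit warm starts skip it
  start_list <- if (is.null(starts)) list(integer(0)) else list()
  # marginal screen: top-K standardized cross-correlations
  marg <- abs(cvec) / sqrt(pmax(diag(G), .Machine$double.eps))
  if (!is.null(exclude)) marg[exclude] <- -Inf
  start_list <- c(start_list, list(as.integer(order(marg, decreasing = TRUE)[
    seq_len(min(K, sum(is.finite(marg))))] - 1L)))
  if (!is.null(starts)) {
    start_list <- c(start_list,
                    lapply(starts, function(s) as.integer(s) - 1L))
  } else if (!is.null(X)) {
    start_list <- c(start_list,
                    lapply(lasso_start_supports(X, y, exclude),
                           function(s) s - 1L))
  }

  res <- tlp_search_cpp(G, cvec, yty, as.integer(K), l0, start_list,
                        as.integer(max_moves))
  active <- sort(res$support + 1L)
  idx <- sort(unique(c(exclude, active)))
  k_used <- length(idx)
  sigma2 <- if (n > k_used) res$rss / (n - k_used) else NA_real_
  se_ex <- NA_real_
  if (!is.null(exclude) && is.finite(sigma2)) {
    Vi <- solve(G[idx, idx, drop = FALSE])
    se_ex <- sqrt(sigma2 * Vi[match(exclude, idx), match(exclude, idx)])
  }
  beta <- drop(res$beta)
  pen <- sum(pmin(abs(beta[setdiff(seq_len(p), exclude)]) / tau, 1))
  structure(list(beta = beta, active = active, K = K, tau = tau,
                 exclude = exclude, objective = res$rss, rss = res$rss,
                 sigma2 = sigma2, se_excluded = se_ex,
                 penalty_value = pen,
                 trajectory = res$trajectory,
                 converged = (length(res$trajectory) - 1L) < max_moves,
                 n = n, p = p),
            class = "flush_tlp")
}

#' @export
print.flush_tlp <- function(x, ...) {
  cat(sprintf("<TLP fit: K = %d, tau = %.4g, active {%s}, RSS = %.6g>\n",
              x$K, x$tau, paste(x$active, collapse = ", "), x$objective))
  invisible(x)
}

#' Choose the constraint size by cross-validation
#'
#' Picks `K` from `K_grid` by 5-fold cross-validated prediction error of the
#' constrained fit, the holdout-based tuning used when `K` is not supplied to
#' the regression inference procedure. Ties go to the smaller `K`.
#'
#' @param X,y design and response (typically the holdout part).
#' @param exclude coordinate kept unpenalized.
#' @param K_grid candidate constraint sizes.
#' @param folds number of folds.
#' @param tau truncation threshold (see [tlp_regression()]).
#' @param seed seed for the fold assignment.
#' @return The selected `K` (integer).
#' @export
cv_choose_K <- function(X, y, exclude = NULL,
                        K_grid = seq_len(min(6L, ncol(X) - 2L)),
                        folds = 5L, tau = NULL, seed = NULL) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  tau <- tau %||% (0.01 * sqrt(log(p) / n))
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- numeric(length(K_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    starts <- lasso_start_supports(Xtr, ytr, exclude, max_starts = 4L)
    G <- crossprod(Xtr); cvec <- drop(crossprod(Xtr, ytr))
    for (k in seq_along(K_grid)) {
      fit <- tlp_regression_gram(G, cvec, sum(ytr^2), sum(tr), K_grid[k],
                                 tau, exclude, starts = starts)
      err[k] <- err[k] +
        sum((y[!tr] - X[!tr, , drop = FALSE] %*% fit$beta)^2)
    }
  }
  as.integer(K_grid[which.min(err)])
}
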
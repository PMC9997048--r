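#' One-sample Kolmogorov check against a target distribution
#'
#' Computes the exact one-sample Kolmogorov statistic
#' `sup_x |F_n(x) - R(x)|` against a target CDF and the asymptotic p-value,
#' with an `alpha`-level decision. Used to audit that perturbed output
#' follows its target.
#'
#' @param sample numeric sample (`n >= 10`).
#' @param target a `flush_target`.
#' @param alpha decision level.
#' @return A list with `statistic`, `p_value`, `reject`, `n`.
#' @export
ks_check <- function(sample, target, alpha = 0.05) {
  n <- length(sample)
  if (n < 10L) stop_df("degenerate sample: need at least 10 observations")
  if (!inherits(target, "flush_target")) stop_df("`target` must be a flush_target")
  x <- sort(sample)
  Fx <- target_cdf(target, x)
  i <- seq_len(n)
  stat <- max(i / n - Fx, Fx - (i - 1) / n)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * stat
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(1, max(0, p))
  list(statistic = stat, p_value = p, reject = p < alpha, n = n,
       alpha = alpha)
}

#' Spearman rank correlation between raw and perturbed values
#'
#' The identifier-preservation diagnostic: the rank correlation between the
#' raw first component and its perturbed copy tends to 1 as the noise scale
#' vanishes. Ties are handled by midranks.
#'
#' @param raw,perturbed numeric vectors of equal length (`>= 3`).
#' @return Spearman's rho.
#' @export
spearman_check <- function(raw, perturbed) {
  if (length(raw) != length(perturbed) || length(raw) < 3L)
    stop_df("`raw` and `perturbed` must have equal length >= 3")
  cor(raw, perturbed, method = "spearman")
}

#' Audit a perturbed copy against the raw data
#'
#' Per-variable distribution comparison between a raw table and one
#' perturbed copy: Kolmogorov statistics for continuous/empirical columns,
#' chi-square statistics on level counts for binary/nominal columns (the
#' Kolmogorov statistic is ill-suited to few-level discrete data), the
#' Spearman rho of the identifier component, and summary means/SDs. All
#' statistics are invariant to the row order of either input.
#'
#' @param raw data frame of raw records.
#' @param perturbed data frame of one perturbed copy.
#' @param schema a `flush_schema`.
#' @param order variable ordering used for the identifier component; defaults
#'   to schema order.
#' @return An object of class `flush_audit` (a list of per-variable rows plus
#'   the identifier correlation), serializable with [write_audit()].
#' @export
audit_perturbation <- function(raw, perturbed, schema, order = NULL) {
  order <- order %||% schema_vars(schema)
  rows <- lapply(order, function(v) {
    ty <- schema$types[[v]]
    if (is_discrete_type(ty)) {
      lev <- sort(unique(c(as.character(raw[[v]]), as.character(perturbed[[v]]))))
      tab <- rbind(raw = table(factor(as.character(raw[[v]]), lev)),
                   pert = table(factor(as.character(perturbed[[v]]), lev)))
      chi <- suppressWarnings(stats::chisq.test(tab))
      list(variable = v, type = ty, statistic = unname(chi$statistic),
           p_value = unname(chi$p.value), test = "chi-square")
    } else {
      ks <- suppressWarnings(stats::ks.test(raw[[v]], perturbed[[v]]))
      list(variable = v, type = ty, statistic = unname(ks$statistic),
           p_value = unname(ks$p.value), test = "ks",
           mean_raw = mean(raw[[v]]), sd_raw = sd(raw[[v]]),
           mean_pert = mean(perturbed[[v]]), sd_pert = sd(perturbed[[v]]))
    }
  })
  v1 <- order[1L]
  rho <- if (nrow(raw) == nrow(perturbed) && nrow(raw) >= 3) {
    a <- raw[[v1]]; b <- perturbed[[v1]]
    if (!is.numeric(a)) a <- as.integer(factor(as.character(a)))
    if (!is.numeric(b)) b <- as.integer(factor(as.character(b),
                                               levels = levels(factor(as.character(raw[[v1]])))))
    spearman_check(as.numeric(a), as.numeric(b))
  } else NA_real_
  structure(list(variables = rows, identifier_spearman = rho,
                 n_raw = nrow(raw), n_perturbed = nrow(perturbed)),
            class = "flush_audit")
}

#' Serialize and reload audit reports
#' @param audit a `flush_audit`.
#' @param path JSON file path.
#' @export
write_audit <- function(audit, path) {
  jsonlite::write_json(unclass(audit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_audit
#' @export
read_audit <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "flush_audit")
}

#' @export
print.flush_audit <- function(x, ...) {
  cat(sprintf("<perturbation audit: %d variables, identifier Spearman rho %.4f>\n",
              length(x$variables), as.numeric(x$identifier_spearman)))
  for (r in x$variables)
    cat(sprintf("  %-10s %-10s %s stat %.4f (p = %.3g)\n",
                r$variable, r$type, r$test, as.numeric(r$statistic),
                as.numeric(r$p_value)))
  invisible(x)
}

#' Empirical coverage of the Monte-Carlo regression intervals
#'
#' Repeatedly simulates the AR(1)-design linear model, runs the full
#' interval-construction procedure for each requested coefficient (with an
#' independently simulated holdout sample of the same size), and reports the
#' percentage of replications whose interval contains the true coefficient,
#' with its binomial Monte-Carlo standard error.
#'
#' @param reps number of replications.
#' @param n,p,beta,sigma,rho simulation configuration (see
#'   [gen_highdim_regression()]).
#' @param coefs coefficients (1-based) to cover.
#' @param D Monte-Carlo size per interval.
#' @param epsilon noise privacy factor.
#' @param alpha significance level.
#' @param K constraint size; cross-validated on each holdout when `NULL`.
#' @param seed integer root seed.
#' @return An object of class `flush_coverage`: per-coefficient coverage (in
#'   percent), binomial SEs, and the configuration echo.
#' @export
coverage_simulation <- function(reps, n = 100L, p = 50L,
                                beta = c(rep(1, 3), rep(0, p - 3)),
                                sigma = 0.5, rho = 0.5,
                                coefs = c(1L, 4L), D = 1000L,
                                epsilon = 0.01, alpha = 0.05, K = NULL,
                                seed = NULL) {
  stopifnot(reps >= 1)
  hits <- matrix(NA, reps, length(coefs),
                 dimnames = list(NULL, paste0("beta", coefs)))
  for (r in seq_len(reps)) {
    sr <- derive_seed(seed, paste0("rep", r))
    dat <- gen_highdim_regression(n, p, beta, sigma, rho,
                                  seed = derive_seed(sr, "data"))
    hold <- gen_highdim_regression(n, p, beta, sigma, rho,
                                   seed = derive_seed(sr, "holdout"))
    for (k in seq_along(coefs)) {
      l <- coefs[k]
      res <- tryCatch(
        flush_ci_for_regression(dat$X, dat$y, l = l, D = D,
                                epsilon = epsilon, alpha = alpha,
                                holdout = list(X = hold$X, y = hold$y),
                                K = K, seed = derive_seed(sr, paste0("ci", l))),
        error = function(e) NULL)
      if (!is.null(res))
        hits[r, k] <- res$ci[1L] <= beta[l] && beta[l] <= res$ci[2L]
    }
  }
  cov <- 100 * colMeans(hits, na.rm = TRUE)
  nrep <- colSums(!is.na(hits))
  se <- 100 * sqrt(cov / 100 * (1 - cov / 100) / pmax(nrep, 1))
  structure(list(coverage = cov, se = se, reps = nrep,
                 hits = hits,
                 config = list(n = n, p = p, D = D, epsilon = epsilon,
                               alpha = alpha, sigma = sigma, rho = rho,
                               coefs = coefs, seed = seed)),
            class = "flush_coverage")
}

#' @export
print.flush_coverage <- function(x, ...) {
  cat(sprintf("<coverage simulation: %d replications, n = %d, p = %d, D = %d>\n",
              max(x$reps), x$config$n, x$config$p, x$config$D))
  for (k in seq_along(x$coverage))
    cat(sprintf("  %s: %.1f%% (binomial SE %.1f)\n",
                names(x$coverage)[k], x$coverage[k], x$se[k]))
  invisible(x)
}

#' Kolmogorov distance of the perturbed pivotal law from Student's t
#'
#' Runs the normal-mean Monte-Carlo pivotal simulation (Laplace noise of
#' scale `1/epsilon`, plug-in target `N(Ybar, S^2)`) on one fixed normal
#' sample of size `n`, and returns the Kolmogorov distance between the `D`
#' perturbed pivotal draws and the `t` distribution on `n - 1` degrees of
#' freedom — which the conditional law of the perturbed pivotal equals
#' exactly, for any raw sample.
#'
#' @param n raw sample size (`>= 2`).
#' @param D Monte-Carlo size.
#' @param epsilon noise privacy factor.
#' @param seed integer seed.
#' @return A list with `ks`, `n`, `D` and the `t_star` draws.
#' @export
pivotal_density_check <- function(n, D, epsilon = 0.01, seed = NULL) {
  if (n < 2) stop_df("`n` must be at least 2")
  z <- with_seed(derive_seed(seed, "sample"), rnorm(n))
  plan <- perturbation_plan(make_noise_model("laplace", 1 / epsilon),
                            m = 1L, seed = derive_seed(seed, "mc"))
  mc <- monte_carlo_pivotal(z, normal_mean_spec(), D, plan)
  x <- sort(mc$t_star)
  i <- seq_along(x)
  Ft <- pt(x, df = n - 1)
  ks <- max(i / length(x) - Ft, Ft - (i - 1) / length(x))
  list(ks = ks, n = n, D = D, t_star = mc$t_star)
}
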
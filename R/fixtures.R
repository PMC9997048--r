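#' Simulate high-dimensional regression data
#'
#' Draws rows of `X` i.i.d. from `N(0, Sigma)` with the AR(1) covariance
#' `Sigma_jk = rho^|j-k|` (via its Cholesky factor) and responses
#' `y = X beta + N(0, sigma^2)` noise. The default coefficient vector places
#' `beta_1 = beta_2 = beta_3 = 1` with all other coefficients zero, with
#' `sigma = 0.5` and `rho = 0.5` — the coverage-study configuration.
#'
#' @param n sample size.
#' @param p number of predictors.
#' @param beta coefficient vector of length `p`.
#' @param sigma error standard deviation (`> 0`, or 0 for noiseless data).
#' @param rho AR(1) correlation, `|rho| < 1`.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list with `X`, `y` and `truth = list(beta, sigma, rho)`.
#' @export
gen_highdim_regression <- function(n, p,
                                   beta = c(rep(1, 3), rep(0, p - 3)),
                                   sigma = 0.5, rho = 0.5, seed = NULL) {
  stopifnot(n >= 1, p >= 1, length(beta) == p)
  if (abs(rho) >= 1) stop_df("`rho` must satisfy |rho| < 1")
  if (sigma < 0) stop_df("`sigma` must be nonnegative")
  with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    X <- if (p == 1L || rho == 0) Z else {
      Sig <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
      Z %*% chol(Sig)
    }
    y <- drop(X %*% beta) + if (sigma > 0) rnorm(n, sd = sigma) else 0
    list(X = X, y = y, truth = list(beta = beta, sigma = sigma, rho = rho))
  })
}

#' Default mixed-type survey schema
#'
#' A 17-variable layout of one empirical age variable, one continuous
#' log-scale income variable, several binary indicators and multi-level
#' nominal variables with realistic level counts, plus a positive integer
#' person-weight column — the shape of demographic survey microdata that the
#' privatization workflow is designed for.
#'
#' @return A `flush_schema` with 17 perturbed variables and weight `PERWT`.
#' @export
survey_schema <- function() {
  flush_schema(
    types = c(
      AGE = "empirical", REGION = "nominal", METPOP = "empirical",
      METRO = "nominal", MORTGAGE = "nominal", SEX = "binary",
      MARST = "nominal", RACE = "nominal", HISPAN = "binary",
      SPEAKENG = "nominal", HCOVANY = "binary", EDUC = "nominal",
      EMPSTAT = "nominal", OCC = "nominal", MIGRATE = "nominal",
      VETSTAT = "binary", INCOME = "continuous"),
    weight = "PERWT")
}

#' Simulate mixed-type weighted survey microdata
#'
#' Generates a synthetic table matching [survey_schema()] (or a custom
#' schema-shaped template) with planted cross-dependencies: employment and
#' insurance depend logistically on age, income depends log-linearly on age
#' and education, and nominal variables carry age-driven multinomial
#' probabilities. Weights are positive integers. This synthetic stand-in
#' emulates the shape of demographic survey extracts; it is generated, not
#' derived from any real survey records.
#'
#' @param n number of rows (`>= 50`).
#' @param schema_template a `flush_schema`; only [survey_schema()]-shaped
#'   templates are generated.
#' @param seed integer seed.
#' @return A list with `data` (data frame) and `schema`.
#' @export
gen_survey_microdata <- function(n, schema_template = survey_schema(),
                                 seed = NULL) {
  if (n < 50) stop_df("`n` must be at least 50")
  sc <- schema_template
  with_seed(seed, {
    age <- pmin(94, pmax(18, round(rnorm(n, 50.8, 19.2))))
    zage <- (age - 50) / 19
    multi <- function(k, shift = 0) {
      # age-tilted multinomial over k levels
      base <- exp(-(seq_len(k) - 1) / 2.5)
      pr <- sapply(seq_len(k), function(j)
        base[j] * exp(0.15 * shift * zage * (j - (k + 1) / 2)))
      pr <- pr / rowSums(pr)
      lev <- sprintf("L%02d", seq_len(k))
      factor(lev[max.col(t(apply(pr, 1L, cumsum)) >= runif(n),
                         ties.method = "first")], levels = lev)
    }
    educ <- multi(7, shift = -1)
    d <- data.frame(
      AGE = age,
      REGION = multi(9),
      METPOP = round(exp(rnorm(n, 13.5, 1.2))),
      METRO = multi(5),
      MORTGAGE = multi(3, shift = 1),
      SEX = rbinom(n, 1, 0.5),
      MARST = multi(6, shift = 1),
      RACE = multi(6),
      HISPAN = rbinom(n, 1, plogis(-2 - 0.3 * zage)),
      SPEAKENG = multi(3),
      HCOVANY = rbinom(n, 1, plogis(2 + 0.8 * zage)),
      EDUC = educ,
      EMPSTAT = multi(3, shift = 2),
      OCC = multi(13),
      MIGRATE = multi(3, shift = -1),
      VETSTAT = rbinom(n, 1, plogis(-3 + 0.9 * zage)),
      stringsAsFactors = FALSE)
    d$INCOME <- round(exp(10 + 0.2 * zage - 0.02 * zage^2 +
                            0.15 * as.integer(educ) + rnorm(n, 0, 0.7)), 2)
    d$PERWT <- 1L + rpois(n, 24)
    list(data = d, schema = sc)
  })
}

#' Simulate Poisson GLM count data
#'
#' Counts `~ Poisson(exp(eta))` with `eta = X (beta / covariate_sd)` and
#' covariates drawn `N(0, covariate_sd^2)`: large-spread covariates are
#' compensated inside the linear predictor (the coefficients are inversely
#' scaled) so the rate stays bounded and comparisons across covariate spreads
#' remain interpretable. The linear predictor is clipped at `log(1e8)` as a
#' guard; clipping never triggers at the default configurations and the
#' number of clipped values is reported.
#'
#' @param n,p sample size and number of covariates.
#' @param beta coefficient vector (on the standardized scale).
#' @param covariate_sd standard deviation of each covariate (e.g. 1, 10, 100).
#' @param seed integer seed.
#' @return A list with `X`, `counts`, `truth` and `n_clipped`.
#' @export
gen_poisson_glm <- function(n, p = length(beta), beta = rep(0.5, 3),
                            covariate_sd = 1, seed = NULL) {
  stopifnot(n >= 1, length(beta) == p)
  check_scalar(covariate_sd, "covariate_sd", positive = TRUE)
  with_seed(seed, {
    X <- matrix(rnorm(n * p, sd = covariate_sd), n, p)
    eta <- drop(X %*% (beta / covariate_sd))
    n_clipped <- sum(eta > log(1e8))
    eta <- pmin(eta, log(1e8))
    list(X = X, counts = rpois(n, exp(eta)),
         truth = list(beta = beta, covariate_sd = covariate_sd),
         n_clipped = n_clipped)
  })
}
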
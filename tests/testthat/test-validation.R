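test_that("ks_check separates matching and mismatched targets", {
  set.seed(71)
  x <- rnorm(1e4)
  ok <- ks_check(x, target_normal(0, 1), alpha = 0.001)
  expect_lt(ok$statistic, 1.95 / sqrt(1e4))
  expect_false(ok$reject)
  bad <- ks_check(x + 1, target_normal(0, 1))
  expect_true(bad$reject)
  # constant sample against a continuous target: statistic at least 1/2
  expect_gte(ks_check(rep(0, 100), target_normal(0, 1))$statistic, 0.5)
  expect_error(ks_check(rnorm(5), target_normal(0, 1)), "degenerate")
})

test_that("spearman_check handles perfect, reversed and tied rankings", {
  expect_equal(spearman_check(1:10, (1:10)^3), 1)
  expect_equal(spearman_check(1:10, -(1:10)), -1)
  expect_equal(spearman_check(c(1, 1, 2), c(1, 1, 2)), 1) # midranks
  expect_error(spearman_check(1:3, 1:4), "equal length")
})

test_that("identifier linkage strengthens monotonically as noise vanishes", {
  set.seed(72)
  scales <- c(1, 0.1, 0.01, 0.001)
  z <- rnorm(1000)
  rho <- vapply(scales, function(b) {
    plan <- perturbation_plan(make_noise_model("laplace", b), m = 5)
    out <- perturb_univariate(z, target_normal(0, 1), plan)
    mean(apply(out$values, 2, spearman_check, raw = z))
  }, numeric(1))
  expect_true(all(diff(rho) > 0))
  expect_gt(rho[4], 0.99)
})

test_that("audit reports are order-invariant and serialize losslessly", {
  sim <- gen_survey_microdata(300, seed = 73)
  ch <- fit_conditional_chain(sim$data, sim$schema)
  plan <- perturbation_plan(make_noise_model("laplace", 0.05), seed = 74)
  pert <- perturb_multivariate(sim$data, ch, plan)$values[[1]]
  a1 <- audit_perturbation(sim$data, pert, sim$schema)
  shuffle <- sample(nrow(pert))
  a2 <- audit_perturbation(sim$data, pert[shuffle, ], sim$schema)
  s1 <- vapply(a1$variables, `[[`, numeric(1), "statistic")
  s2 <- vapply(a2$variables, `[[`, numeric(1), "statistic")
  expect_equal(s1, s2)
  f <- tempfile(fileext = ".json")
  write_audit(a1, f)
  back <- read_audit(f)
  expect_equal(vapply(back$variables, `[[`, numeric(1), "statistic"), s1)
  expect_equal(as.numeric(back$identifier_spearman), a1$identifier_spearman)
  unlink(f)
})

test_that("pivotal density check degrades gracefully at tiny D", {
  pc <- pivotal_density_check(4, D = 10, seed = 75)
  expect_true(is.finite(pc$ks))
  expect_length(pc$t_star, 10)
})

test_that("privatization costs accuracy: raw fit beats privatized fit in KL", {
  # Poisson regression refit on raw vs privatized covariate/count table;
  # KL between true and fitted mean counts must be ordered raw < privatized.
  set.seed(76)
  sim <- gen_poisson_glm(2000, beta = c(0.5, -0.3, 0.2), seed = 76)
  d <- data.frame(sim$X, count = sim$counts)
  names(d) <- c("x1", "x2", "x3", "count")
  sc <- flush_schema(c(x1 = "empirical", x2 = "empirical", x3 = "empirical",
                       count = "empirical"))
  pv <- privatize(d, sc, epsilon = 1, seed = 77)
  rel <- d[pv$release_rows, ]
  priv <- pv$perturbed$values[[1]]
  priv$count <- round(pmax(priv$count, 0))
  truth_eta <- function(X) drop(as.matrix(X) %*% c(0.5, -0.3, 0.2))
  kl <- function(fitdat) {
    fit <- suppressWarnings(glm(count ~ x1 + x2 + x3 - 1,
                                family = stats::poisson(), data = fitdat))
    lam_t <- exp(truth_eta(rel[, 1:3]))
    lam_h <- exp(drop(as.matrix(rel[, 1:3]) %*% coef(fit)))
    mean(lam_t * log(lam_t / lam_h) - lam_t + lam_h)
  }
  expect_lt(kl(rel), kl(priv))
})
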
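test_that("bias correction reproduces the printed arithmetic", {
  expect_equal(bias_correct(1, c(1.1, 0.9, 1.3, 0.7)),
               list(bias = 0, theta_c = 1))
  expect_equal(bias_correct(2, c(2.5, 2.5)),
               list(bias = 0.5, theta_c = 2.5))
  expect_equal(bias_correct(3, rep(3, 10)), list(bias = 0, theta_c = 3))
  # classical sign flag
  expect_equal(bias_correct(2, c(2.5, 2.5), sign = "classical")$theta_c, 1.5)
  expect_error(bias_correct(1, numeric(0)), "no perturbed")
})

test_that("interval inversion is exact for analytically supplied quantiles", {
  q <- qt(0.975, df = 4)
  ci <- confidence_interval(0, 1, alpha = 0.05, quantiles = c(-q, q))
  expect_equal(unname(ci), c(-q, q))
  # general location/scale: [theta_c - q_hi se, theta_c - q_lo se]
  ci2 <- confidence_interval(1.2, 0.3, alpha = 0.1, quantiles = c(-1, 2))
  expect_equal(unname(ci2), c(1.2 - 2 * 0.3, 1.2 + 1 * 0.3))
  # two-point draws at +/- q with matching quantiles give exactly [-q, q]
  draws <- rep(c(-2, 2), each = 20)
  ci3 <- confidence_interval(0, 1, draws, alpha = 0.5)
  expect_equal(unname(ci3), c(-2, 2))
  expect_error(confidence_interval(0, 1, rnorm(5), alpha = 0.01), "few")
})

test_that("a constant estimator yields identically zero pivotal draws", {
  spec <- pivotal_spec(
    estimate = function(z) list(theta = 42, se = 1),
    pivotal = function(est, theta) (est$theta - theta) / est$se,
    target = function(est, z) target_normal(0, 1))
  plan <- perturbation_plan(make_noise_model("laplace", 1), seed = 51)
  mc <- monte_carlo_pivotal(rnorm(30), spec, D = 50, plan)
  expect_equal(mc$t_star, rep(0, 50))
  expect_equal(mc$theta_star, rep(42, 50))
})

test_that("perturbed normal-mean pivotal is t-distributed (quantile check)", {
  set.seed(52)
  z <- rnorm(5, mean = 3, sd = 2)
  plan <- perturbation_plan(make_noise_model("laplace", 100), seed = 53)
  mc <- monte_carlo_pivotal(z, normal_mean_spec(), D = 2e4, plan)
  q <- quantile(mc$t_star, 0.975, names = FALSE)
  # quantile-estimate SE at D = 2e4: sqrt(p(1-p)/D)/f(q) ~ 0.06
  expect_lt(abs(q - qt(0.975, df = 4)), 0.2)
  # and the mean-centring works: theta* centre near the sample mean
  expect_lt(abs(mean(mc$theta_star) - mean(z)) / (sd(z) / sqrt(5)), 0.2)
})

test_that("estimator failures are dropped, replaced and counted", {
  flaky_env <- new.env()
  flaky_env$k <- 0L
  spec <- pivotal_spec(
    estimate = function(z) {
      flaky_env$k <- flaky_env$k + 1L
      if (flaky_env$k %% 7L == 0L) stop("numerical failure")
      list(theta = mean(z), se = sd(z) / sqrt(length(z)))
    },
    pivotal = function(est, theta) (est$theta - theta) / est$se,
    target = function(est, z) target_normal(mean(z), sd(z)))
  plan <- perturbation_plan(make_noise_model("laplace", 1), seed = 54)
  mc <- monte_carlo_pivotal(rnorm(20), spec, D = 40, plan)
  expect_length(mc$t_star, 40)
  expect_gt(mc$n_failed, 0)
})

test_that("the full normal-mean interval behaves like a t interval", {
  set.seed(55)
  z <- rnorm(15, mean = 10)
  res <- flush_mean_ci(z, D = 5000, seed = 56)
  classical <- mean(z) + qt(c(0.025, 0.975), 14) * sd(z) / sqrt(15)
  expect_lt(abs(res$ci[1] - classical[1]), 0.25 * diff(classical))
  expect_lt(abs(res$ci[2] - classical[2]), 0.25 * diff(classical))
  expect_true(res$ci[1] < res$theta_c && res$theta_c < res$ci[2])
  # deterministic under a fixed seed
  res2 <- flush_mean_ci(z, D = 5000, seed = 56)
  expect_identical(res$ci, res2$ci)
})

test_that("regression inference is seeded-reproducible and sane on easy data", {
  sim <- gen_highdim_regression(80, 8, beta = c(2, rep(0, 7)), sigma = 0.3,
                                seed = 57)
  hold <- gen_highdim_regression(80, 8, beta = c(2, rep(0, 7)), sigma = 0.3,
                                 seed = 58)
  a <- flush_ci_for_regression(sim$X, sim$y, l = 1, D = 200, K = 2,
                               holdout = list(X = hold$X, y = hold$y),
                               seed = 59)
  b <- flush_ci_for_regression(sim$X, sim$y, l = 1, D = 200, K = 2,
                               holdout = list(X = hold$X, y = hold$y),
                               seed = 59)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] < 2 & 2 < a$ci[2])
  expect_lt(a$ci[2] - a$ci[1], 1)
})
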
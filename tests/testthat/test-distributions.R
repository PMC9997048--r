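test_that("noise models have mutually consistent CDF, density and quantile", {
  for (fam in c("laplace", "gaussian", "uniform")) {
    for (b in c(0.5, 1, 17)) {
      nm <- make_noise_model(fam, b)
      expect_equal(noise_cdf(nm, 0), 0.5)
      # closed-form CDF agrees with quadrature of the density
      xs <- c(-1.3, -0.2, 0.4, 2.1) * b
      expect_equal(noise_cdf(nm, xs), noise_cdf_quadrature(nm, xs),
                   tolerance = 1e-7)
      # quantile inverts the CDF over the central mass
      us <- c(0.0001, 0.025, 0.5, 0.9, 0.9999)
      expect_equal(noise_cdf(nm, noise_quantile(nm, us)), us,
                   tolerance = 1e-8)
    }
  }
  # closed-form Laplace value: CDF(-2 log 2, b = 2) = 0.25
  expect_equal(noise_cdf(make_noise_model("laplace", 2), -2 * log(2)), 0.25)
  expect_error(make_noise_model("laplace", 0), "positive")
  expect_error(make_noise_model("cauchy", 1))
})

test_that("convolved CDF matches Monte-Carlo, is symmetric and invertible", {
  g <- convolve_uniform_noise(make_noise_model("laplace", 1))
  # Monte-Carlo oracle at t = 1.5
  set.seed(42)
  n_mc <- 1e6
  draws <- runif(n_mc) + noise_sample(make_noise_model("laplace", 1), n_mc)
  phat <- mean(draws <= 1.5)
  se <- sqrt(phat * (1 - phat) / n_mc)
  expect_lt(abs(convolved_cdf(g, 1.5) - phat), 3 * se)
  # symmetry G(t) + G(1 - t) = 1 on a grid, for every family
  for (fam in c("laplace", "gaussian", "uniform")) {
    gf <- convolve_uniform_noise(make_noise_model(fam, 0.7))
    ts <- seq(-3, 4, by = 0.25)
    expect_equal(convolved_cdf(gf, ts) + convolved_cdf(gf, 1 - ts),
                 rep(1, length(ts)), tolerance = 1e-10)
    expect_equal(convolved_cdf(gf, 0.5), 0.5)
  }
  # inverse round-trip to numeric tolerance
  ts <- c(-2, -0.3, 0.2, 0.5, 0.9, 1.7, 3)
  expect_equal(convolved_quantile(g, convolved_cdf(g, ts)), ts,
               tolerance = 1e-8)
  # vanishing noise: G approaches the Uniform[0,1] CDF
  g0 <- convolve_uniform_noise(make_noise_model("laplace", 1e-9))
  expect_equal(convolved_cdf(g0, c(0.1, 0.5, 0.93)), c(0.1, 0.5, 0.93),
               tolerance = 1e-6)
  expect_equal(convolved_cdf(g0, c(-0.5, 1.5)), c(0, 1), tolerance = 1e-6)
})

test_that("G(U + e) is uniform: the transform law behind distribution preservation", {
  set.seed(7)
  n <- 1e5
  nm <- make_noise_model("gaussian", 0.5)
  g <- convolve_uniform_noise(nm)
  x <- runif(n) + noise_sample(nm, n)
  ks <- suppressWarnings(stats::ks.test(convolved_cdf(g, x), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("smoothed empirical CDF agrees with the empirical CDF at jumps", {
  r <- fit_smoothed_cdf(c(0, 1))
  expect_equal(target_cdf(r, c(0, 1)), c(0.5, 1))
  r3 <- fit_smoothed_cdf(c(1, 2, 3))
  expect_equal(target_cdf(r3, c(1, 2, 3)), c(1, 2, 3) / 3)
  # weighted: jump masses proportional to weights
  rw <- fit_smoothed_cdf(c(1, 2, 3), weights = c(1, 1, 2))
  expect_equal(target_cdf(rw, c(1, 2, 3)), c(0.25, 0.5, 1))
  # strictly increasing and continuous between extreme jumps
  xs <- seq(1, 3, by = 0.01)
  expect_true(all(diff(target_cdf(r3, xs)) > 0))
  # generalized-inverse contract on a continuous target
  us <- seq(0.01, 0.99, by = 0.01)
  expect_equal(target_cdf(r3, target_quantile(r3, us)), us, tolerance = 1e-12)
  expect_error(fit_smoothed_cdf(rep(2, 5)), "degenerate")
})

test_that("smoothed CDF of a large normal sample is Kolmogorov-close to the truth", {
  set.seed(11)
  r <- fit_smoothed_cdf(rnorm(1e4))
  xs <- seq(-4, 4, by = 0.005)
  # DKW at n = 1e4: the empirical CDF is within 0.0136 of truth w.p. 0.975,
  # and the smoothing moves it by at most one jump mass
  expect_lt(max(abs(target_cdf(r, xs) - pnorm(xs))), 0.03)
})

test_that("parametric targets satisfy the quantile/cdf contracts", {
  for (tg in list(target_normal(2, 3), target_exponential(0.5),
                  target_uniform(-1, 4))) {
    us <- seq(0.02, 0.98, by = 0.02)
    expect_equal(target_cdf(tg, target_quantile(tg, us)), us,
                 tolerance = 1e-10)
  }
})

test_that("conditional chain: independent columns give a flat conditional mean", {
  set.seed(21)
  n <- 1e4
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  sc <- flush_schema(c(a = "continuous", b = "continuous"))
  ch <- fit_conditional_chain(d, sc)
  fit <- ch$models[["b"]]$fit
  sl <- summary(fit)$coefficients["a", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])
  # builder is a pure function of the prefix: same prefix, same target
  t1 <- conditional_target(ch, 2, data.frame(a = 0.5))
  t2 <- conditional_target(ch, 2, data.frame(a = 0.5))
  expect_equal(target_quantile(t1, 0.3), target_quantile(t2, 0.3))
})

test_that("conditional chain: single column reduces to the smoothed empirical CDF", {
  set.seed(22)
  x <- rnorm(50)
  ch <- fit_conditional_chain(data.frame(x = x),
                              flush_schema(c(x = "empirical")))
  direct <- fit_smoothed_cdf(x)
  us <- c(0.1, 0.37, 0.7, 0.95)
  expect_equal(target_quantile(conditional_target(ch, 1), us),
               target_quantile(direct, us))
})

test_that("conditional chain recovers a planted logistic dependence", {
  set.seed(23)
  n <- 1e4
  z <- rnorm(n)
  b <- rbinom(n, 1, plogis(z))
  d <- data.frame(z = z, b = b)
  ch <- fit_conditional_chain(d, flush_schema(c(z = "continuous",
                                                b = "binary")))
  q <- quantile(z, c(0.25, 0.5, 0.75))
  ph <- predict(ch$models[["b"]]$fit,
                newdata = data.frame(z = as.numeric(q)), type = "response")
  expect_lt(max(abs(ph - plogis(q))), 0.05)
})

test_that("chain fitting validates schema coverage and data shape", {
  d <- data.frame(a = rnorm(10), b = rnorm(10))
  sc <- flush_schema(c(a = "continuous", b = "continuous", c = "binary"))
  expect_error(fit_conditional_chain(d, sc), "missing")
  expect_error(
    fit_conditional_chain(d[1, ], flush_schema(c(a = "continuous",
                                                 b = "continuous"))),
    "at least 2 rows")
  expect_error(flush_schema(c(a = "fancy")), "unsupported")
})
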
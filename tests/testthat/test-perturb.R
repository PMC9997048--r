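test_that("rank-matched uniforms carry the raw sample's ranks", {
  rc <- rank_matched_uniforms(c(3, 1, 2), seed = 1)
  expect_true(rc$u[2] < rc$u[3] && rc$u[3] < rc$u[1])
  one <- rank_matched_uniforms(7.5)
  expect_length(one$u, 1)
  expect_true(one$u > 0 && one$u < 1)
  set.seed(5)
  z <- rnorm(1e4)
  rc <- rank_matched_uniforms(z)
  expect_equal(cor(z, rc$u, method = "spearman"), 1)
  expect_error(rank_matched_uniforms(numeric(0)), "non-empty")
})

test_that("tied raw values get a uniform marginal with seeded tie-breaking", {
  z <- c(1, 1, 1, 2, 2)
  a <- rank_matched_uniforms(z, seed = 9)
  b <- rank_matched_uniforms(z, seed = 9)
  expect_identical(a$u, b$u)
  expect_true(all(a$u[z == 1] < min(a$u[z == 2])))
})

test_that("perturbation reduces to the identity in the zero-noise limit", {
  set.seed(2)
  z <- runif(200)
  plan <- perturbation_plan(make_noise_model("laplace", 1e-12), seed = 3)
  out <- perturb_univariate(z, target_uniform(0, 1), plan)
  # output must equal the rank-coupled uniforms; ranks must match z
  expect_equal(cor(z, out$values[, 1], method = "spearman"), 1)
  expect_lt(ks_distance(out$values[, 1], function(x) pmin(1, pmax(0, x))),
            0.12)
})

test_that("perturbed output follows the target distribution (KS)", {
  set.seed(4)
  z <- rnorm(2000)
  plan <- perturbation_plan(make_noise_model("laplace", 1), m = 5, seed = 5)
  out <- perturb_univariate(z, target_normal(0, 1), plan)
  ks <- suppressWarnings(stats::ks.test(as.vector(out$values), pnorm))
  expect_gt(ks$p.value, 0.001)
})

test_that("copies are reproducible under the plan seed", {
  z <- rnorm(50)
  plan <- perturbation_plan(make_noise_model("gaussian", 0.3), m = 2,
                            seed = 77)
  a <- perturb_univariate(z, target_normal(0, 1), plan)
  b <- perturb_univariate(z, target_normal(0, 1), plan)
  expect_identical(a$values, b$values)
})

test_that("records are independent across rows and exchangeable across copies", {
  set.seed(6)
  n <- 400; m <- 50
  z <- rnorm(n)
  plan <- perturbation_plan(make_noise_model("laplace", 0.5), m = m, seed = 8)
  out <- perturb_univariate(z, target_normal(0, 1), plan)$values
  # cross-record correlation within a copy is near zero
  r <- cor(t(out[seq(1, 100), ]))
  off <- r[upper.tri(r)]
  expect_lt(mean(abs(off)), 0.2)
  expect_lt(abs(mean(off)), 0.02)
})

test_that("residual perturbation recentres on the fitted means", {
  set.seed(9)
  n <- 500
  x <- rnorm(n)
  mu <- 1 + 2 * x
  y <- mu + rnorm(n, sd = 0.7)
  plan <- perturbation_plan(make_noise_model("laplace", 100), m = 20,
                            seed = 10)
  out <- perturb_residuals(y, mu, sigma2_hat = 0.49, plan,
                           coupling = "fresh")
  eps <- out$values - mu
  ks <- suppressWarnings(stats::ks.test(as.vector(eps), pnorm, sd = 0.7))
  expect_gt(ks$p.value, 0.001)
  # vanishing residual variance: output collapses to the fitted means
  tiny <- perturb_residuals(y, mu, sigma2_hat = 1e-30, plan)
  expect_equal(tiny$values[, 1], mu, tolerance = 1e-9)
  expect_error(perturb_residuals(y, mu, 0, plan), "positive")
  expect_error(perturb_residuals(y, mu[-1], 1, plan), "length")
})

test_that("multivariate chain perturbation preserves a bivariate correlation", {
  set.seed(12)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2)
  sc <- flush_schema(c(x1 = "continuous", x2 = "continuous"))
  ch <- fit_conditional_chain(d, sc)
  plan <- perturbation_plan(make_noise_model("laplace", 0.01), seed = 13)
  out <- perturb_multivariate(d, ch, plan)$values[[1]]
  expect_lt(abs(cor(out$x1, out$x2) - 0.7), 0.05)
  # marginals preserved too
  expect_gt(suppressWarnings(
    stats::ks.test(out$x1, x1)$p.value), 0.001)
})

test_that("a single-variable chain matches univariate perturbation", {
  set.seed(14)
  z <- rnorm(300)
  sc <- flush_schema(c(z = "empirical"))
  ch <- fit_conditional_chain(data.frame(z = z), sc)
  plan <- perturbation_plan(make_noise_model("laplace", 0.1), seed = 15)
  mv <- perturb_multivariate(data.frame(z = z), ch, plan)$values[[1]]$z
  uv <- perturb_univariate(z, fit_smoothed_cdf(z), plan)$values[, 1]
  expect_equal(mv, uv)
})

test_that("dp mode uses the per-variable budget scale and enforces the holdout", {
  set.seed(16)
  sim <- gen_survey_microdata(300, seed = 16)
  ch <- fit_conditional_chain(sim$data[1:150, ], sim$schema)
  plan <- perturbation_plan(make_noise_model("laplace", 1), dp_mode = TRUE,
                            epsilon = 1, seed = 17)
  out <- perturb_multivariate(sim$data[151:300, ], ch, plan)
  expect_equal(out$budget$scale, 17)
  expect_setequal(out$budget$consumed, schema_vars(sim$schema))
  # perturbing rows the chain saw is a holdout violation
  expect_error(perturb_multivariate(sim$data[1:150, ], ch, plan),
               "holdout violation")
})

test_that("identifiers round-trip through file output", {
  set.seed(18)
  z <- rnorm(25)
  plan <- perturbation_plan(make_noise_model("laplace", 0.2), m = 3,
                            seed = 19)
  out <- perturb_univariate(z, target_normal(0, 1), plan)
  f <- tempfile(fileext = ".csv")
  write_perturbed(out, f)
  back <- read_perturbed(f)
  expect_equal(sort(unique(back$data$.id)), seq_len(25))
  expect_equal(back$provenance$noise$scale, 0.2)
  expect_equal(matrix(back$data$value, 25, 3), out$values,
               tolerance = 1e-12)
  unlink(c(f, paste0(f, ".json")))
})
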
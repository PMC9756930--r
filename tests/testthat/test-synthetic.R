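test_that("generation is reproducible and leaves the caller's RNG alone", {
  a <- generate_series(10, 3, c(50, 2), seed = 42)
  b <- generate_series(10, 3, c(50, 2), seed = 42)
  expect_identical(a$series$y, b$series$y)
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_series(5, 2, c(10, 1), seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("generated series always satisfy the container invariants", {
  set.seed(12)
  for (rep in 1:20) {
    I <- sample(1:15, 1); S <- sample(1:4, 1); K <- sample(1:4, 1)
    sim <- generate_series(I, S, rnorm(K), rho = runif(S, 0.5, 1.2),
                           noise_kind = sample(c("additive", "multiplicative", "none"), 1),
                           noise_sd = runif(1, 0, 2), seed = rep)
    s <- sim$series
    expect_s3_class(s, "scenario_series")
    expect_identical(dim(s$y), c(I, S))
    expect_lt(abs(sum(s$p) - 1), 1e-9)
    expect_true(all(diff(s$x) > 0) || I == 1)
  }
})

test_that("zero noise reproduces the resiliency-scaled trend exactly", {
  sim <- generate_series(8, 3, c(25, 1.5, -0.1), noise_kind = "none", seed = 3)
  expected <- tcrossprod(sim$truth$trend, sim$truth$rho)
  expect_equal(unname(sim$series$y), expected)
  sim0 <- generate_series(8, 3, c(25, 1.5, -0.1), noise_sd = 0, seed = 3)
  expect_equal(unname(sim0$series$y), expected)
})

test_that("band mode brackets the base trend symmetrically", {
  sim <- generate_series(6, 3, c(100, 2), scenario_mode = "band", band = 0.1,
                         noise_kind = "none", seed = 1)
  f <- sim$truth$trend
  expect_equal(unname(sim$series$y[, 1]), 0.9 * f)
  expect_equal(unname(sim$series$y[, 2]), f)
  expect_equal(unname(sim$series$y[, 3]), 1.1 * f)
})

test_that("coefficient recovery error shrinks with the noise level", {
  errs <- vapply(c(0.5, 0.05, 0.005), function(sd) {
    worst <- 0
    for (seed in 1:5) {
      sim <- generate_series(12, 2, c(40, 3, -0.2), noise_kind = "additive",
                             noise_sd = sd, rho = c(0.9, 1), seed = seed)
      f <- rrml_fit(sim$series, rrml_config(degree = 3))
      worst <- max(worst, max(abs(f$a - sim$truth$coefficients)))
    }
    worst
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("fitted objective converges to the half-normal mean under pure noise", {
  # single scenario, beta = 1, uniform weights: the objective estimates
  # E|N(0, sigma)| = sigma * sqrt(2/pi); Monte-Carlo oracle at 1e4 draws
  # confirms the closed form, the fit must sit within 3 standard errors
  sigma <- 2
  n <- 60
  sim <- generate_series(n, 1, c(50, 2, -0.05), rho = 1,
                         noise_kind = "additive", noise_sd = sigma, seed = 21)
  f <- rrml_fit(sim$series, rrml_config(beta = 1, degree = 3))
  theo <- sigma * sqrt(2 / pi)
  mc <- with_seed_local(999, mean(abs(rnorm(1e4, 0, sigma))))
  expect_lt(abs(mc - theo), 3 * sigma * sqrt(1 - 2 / pi) / sqrt(1e4))
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(f$rrmad - theo), 3 * se)
})

test_that("the demo fixture mirrors the documented study shape", {
  s <- demo_production_series()
  expect_identical(dim(s$y), c(21L, 3L))
  expect_equal(s$rho, c(0.85, 0.90, 0.95))
  expect_equal(s$p, rep(1 / 3, 3))
  expect_identical(s$labels, 2001:2021)
  cc <- complexity_counts(n_obs(s), n_scen(s), 7)
  expect_identical(c(cc$binary, cc$positive, cc$free, cc$constraints),
                   c(0L, 252L, 239L, 358L))
  # deterministic and exactly trend-valued at zero noise
  expect_identical(s$y, demo_production_series()$y)
  s0 <- demo_production_series(noise_sd = 0)
  tr <- attr(s0, "truth")
  expect_equal(unname(s0$y), tcrossprod(tr$trend, tr$rho))
})
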
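test_that("built programs have the closed-form size, with zero binaries", {
  s <- demo_production_series()
  lp <- build_lp(s, rrml_profile("main"))
  expect_identical(lp$counts$binary, 0L)
  expect_identical(lp$counts$positive, 252L)
  expect_identical(lp$counts$free, 239L)
  expect_identical(lp$counts$constraints, 358L)
  expect_identical(nrow(lp$A), 358L)
  expect_identical(ncol(lp$A), 252L + 239L)
})

test_that("builder registry matches the closed-form counts on random dimensions", {
  set.seed(33)
  for (rep in 1:100) {
    I <- sample(1:12, 1); S <- sample(1:4, 1); K <- sample(1:5, 1)
    sim <- generate_series(I, S, rnorm(K), rho = runif(S, 0.5, 1),
                           noise_kind = "none", seed = rep)
    lp <- suppressMessages(build_lp(sim$series, rrml_config(degree = K)))
    cc <- complexity_counts(I, S, K)
    expect_identical(lp$counts$positive, cc$positive)
    expect_identical(lp$counts$free, cc$free)
    expect_identical(lp$counts$constraints, cc$constraints)
    expect_identical(lp$counts$binary, 0L)
    expect_true(all(lp$lower %in% c(0, -Inf)))
    # split variables are the nonnegative ones
    split <- grepl("^split", lp$vars$role)
    expect_identical(which(lp$lower == 0), which(split))
  }
})

test_that("the solver finds the weighted-median constant fit", {
  s <- scenario_series(cbind(c(1, 2, 10)), rho = 1)
  cfg <- rrml_config(beta = 1, degree = 1)
  f <- rrml_fit(s, cfg)
  expect_equal(f$a, 2, tolerance = 1e-8)
  expect_equal(f$rrmad, 3, tolerance = 1e-8)
  # independent enumeration oracle: a constant LAD optimum sits on a data point
  cand <- vapply(c(1, 2, 10), function(a) rrmad_evaluate(a, s, cfg), numeric(1))
  expect_equal(f$rrmad, min(cand))
})

test_that("solver statuses distinguish infeasible programs", {
  # x = 1 and x = 2 simultaneously
  bad <- linear_program(A = rbind(1, 1), rhs = c(1, 2), objective = 0)
  expect_identical(solve_lp(bad)$status, "infeasible")
  ok <- linear_program(A = rbind(c(1, 1)), rhs = 2, objective = c(1, 2))
  sol <- solve_lp(ok)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$solution, c(2, 0))
  unb <- linear_program(A = rbind(c(1, -1)), rhs = 0, objective = c(-1, 0))
  expect_identical(solve_lp(unb)$status, "unbounded")
})

test_that("noiseless series are recovered exactly", {
  sim <- generate_series(12, 3, c(40, 3, -0.25), noise_kind = "none", seed = 4)
  f <- rrml_fit(sim$series, rrml_config(degree = 3))
  expect_lt(f$rrmad, 1e-6)
  expect_lt(max(abs(f$a - sim$truth$coefficients) /
                (1 + abs(sim$truth$coefficients))), 1e-5)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("an interpolating fit drives the objective to zero", {
  set.seed(9)
  y <- cbind(50 + cumsum(rnorm(5, 1, 2)))
  s <- scenario_series(y, rho = 1)
  f <- rrml_fit(s, rrml_config(beta = 1, degree = 5))
  expect_lt(f$rrmad, 1e-6)
})

test_that("objective is non-increasing as basis terms are added", {
  inst <- random_instance(77, I = 12, S = 3, K = 3)
  vals <- vapply(2:6, function(K) {
    cfg <- inst$config; cfg$degree <- K
    rrml_fit(inst$series, cfg)$rrmad
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("recomputed diagnostics agree with the LP optimum on random instances", {
  for (rep in 1:20) {
    inst <- random_instance(100 + rep)
    f <- rrml_fit(inst$series, inst$config)
    expect_rel_equal(f$rrmad, f$lp_objective, 1e-6)
    expect_lte(f$tightness_gap, 1e-6 * (1 + max(abs(inst$series$y))))
    # the evaluator at the fitted coefficients is definitionally consistent
    expect_rel_equal(rrmad_evaluate(f$a, inst$series, inst$config), f$rrmad, 1e-12)
  }
})

test_that("no candidate coefficient vector beats the LP optimum", {
  for (rep in 1:20) {
    inst <- random_instance(200 + rep)
    f <- rrml_fit(inst$series, inst$config)
    a_ols <- ols_candidate(inst$series, inst$config)
    expect_gte(rrmad_evaluate(a_ols, inst$series, inst$config), f$rrmad - 1e-6)
    # random perturbations of the optimum do no better either
    for (j in 1:3) {
      a_pert <- f$a + rnorm(length(f$a), 0, 0.1)
      expect_gte(rrmad_evaluate(a_pert, inst$series, inst$config), f$rrmad - 1e-6)
    }
  }
})

test_that("LP optimum matches a dense grid search on tiny instances", {
  set.seed(7)
  for (t in 1:4) {
    I <- sample(3:4, 1); S <- sample(1:2, 1); K <- sample(1:2, 1)
    co <- round(runif(K, -2, 2), 1)
    sim <- generate_series(I, S, co, noise_kind = "additive", noise_sd = 0.3,
                           rho = runif(S, 0.8, 1), seed = 300 + t)
    cfg <- rrml_config(beta = 0.95, alpha = 0.05, degree = K)
    f <- rrml_fit(sim$series, cfg)
    h <- 0.02
    grids <- lapply(seq_len(K), function(k) seq(co[k] - 0.6, co[k] + 0.6, by = h))
    G <- as.matrix(expand.grid(grids))
    vals <- apply(G, 1, function(a) rrmad_evaluate(a, sim$series, cfg))
    expect_lte(f$rrmad, min(vals) + 1e-9)
    # grid resolution bound: objective is piecewise linear with slope bounded
    # by the summed weighted basis magnitudes
    Phi <- basis_matrix(sim$series$x, cfg)
    lip <- sum(abs(Phi)) * max(sim$series$rho)
    expect_lte(min(vals) - f$rrmad, lip * h)
  }
})

test_that("scaling the data scales the objective and fixes R2", {
  inst <- random_instance(55, I = 10, S = 2, K = 3, beta = 0.95, alpha = 0.05)
  f1 <- rrml_fit(inst$series, inst$config)
  s2 <- inst$series; s2$y <- 7 * s2$y
  f2 <- rrml_fit(s2, inst$config)
  expect_rel_equal(f2$rrmad, 7 * f1$rrmad, 1e-8)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
  # the scaled coefficients attain the scaled optimum
  expect_rel_equal(rrmad_evaluate(7 * f1$a, s2, inst$config), f2$rrmad, 1e-8)
})

test_that("weighted LAD special case agrees with an independent quantile fit", {
  skip_if_not_installed("quantreg")
  sim <- generate_series(25, 1, c(30, 1.5, -0.05), rho = 1,
                         noise_kind = "additive", noise_sd = 2, seed = 11)
  cfg <- rrml_config(beta = 1, lambda = 0.8, degree = 3)
  f <- rrml_fit(sim$series, cfg)
  w <- observation_weights(0.8, 25)
  Phi <- basis_matrix(sim$series$x, cfg)
  rq_fit <- quantreg::rq.wfit(Phi, sim$series$y[, 1], weights = w)
  expect_rel_equal(sum(w * abs(rq_fit$residuals)), f$rrmad, 1e-8)
})

test_that("a failing tightness condition triggers a warning, diagnostics stay exact", {
  sim <- generate_series(8, 3, c(20, 1), noise_kind = "additive",
                         noise_sd = 2, seed = 19)
  cfg <- rrml_config(beta = 0.05, alpha = 0.01, degree = 2)
  expect_false(tightness_holds(cfg$alpha, cfg$beta, sim$series$p))
  expect_warning(f <- rrml_fit(sim$series, cfg), "tightness")
  # recomputed objective can exceed the LP bound, never undercut it
  expect_gte(f$rrmad, f$lp_objective - 1e-9)
})

test_that("MPS export round-trips the program dimensions", {
  sim <- generate_series(4, 2, c(10, 1), seed = 2)
  lp <- build_lp(sim$series, rrml_config(degree = 2))
  path <- withr::local_tempfile(fileext = ".mps")
  write_mps(lp, path)
  txt <- readLines(path)
  expect_identical(sum(grepl("^ E ", txt)), nrow(lp$A))
  expect_identical(sum(grepl("^ FR ", txt)), sum(!is.finite(lp$lower)))
  expect_identical(txt[length(txt)], "ENDATA")
})
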
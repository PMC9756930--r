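# experiments run on a deliberately small panel so each driver costs seconds
exp_instance <- function() {
  sim <- generate_series(12, 3, c(60, 4, -0.6, 0.025), rho = rho_ladder(3),
                         noise_kind = "multiplicative", noise_sd = 0.02,
                         seed = 404)
  list(series = sim$series, truth = sim$truth,
       config = rrml_profile("main", degree = 4))
}

test_that("degree scan flattens at the generating degree on noiseless data", {
  sim <- generate_series(12, 3, c(60, 4, -0.6), noise_kind = "none", seed = 5)
  scan <- degree_scan(sim$series, rrml_profile("main", degree = 3), k_range = 2:6)
  rr <- scan$rrmad
  expect_true(all(diff(rr) <= 1e-8))           # nested models never get worse
  expect_true(all(rr[scan$setting >= 3] < 1e-6))
  expect_gt(rr[scan$setting == 2], 1e-3)       # underfitting is visible
  expect_identical(attr(scan, "selected"), 3L) # smallest K at the optimum
})

test_that("degree scan records coefficients and keeps requested order", {
  inst <- exp_instance()
  scan <- degree_scan(inst$series, inst$config, k_range = c(2, 4, 3))
  expect_identical(scan$setting, c(2L, 4L, 3L))
  co <- attr(scan, "coefficients")
  expect_identical(dim(co), c(3L, 4L))
  expect_false(anyNA(co[2, 1:4]))   # K = 4 row fully populated
  expect_true(all(is.na(co[1, 3:4])))
})

test_that("degree scan flags ill-conditioned bases instead of inventing infeasibility", {
  s <- demo_production_series()
  scan <- degree_scan(s, rrml_profile("main"), k_range = c(7, 8))
  expect_true(scan$feasible[scan$setting == 7])
  expect_false(scan$feasible[scan$setting == 8])
  expect_match(scan$note[scan$setting == 8], "ill-conditioned")
})

test_that("basis comparison anchors variation at the polynomial model", {
  inst <- exp_instance()
  cmp <- compare_basis(inst$series, inst$config)
  expect_identical(cmp$setting, c("polynomial", "sine1", "sine2", "sine3"))
  expect_equal(cmp$variation_pct[1], 0)
  expect_true(all(cmp$rrmad >= 0, na.rm = TRUE))
  # omega = pi on integer counters makes the shifted-sine family identical
  expect_rel_equal(cmp$rrmad[cmp$setting == "sine3"],
                   cmp$rrmad[cmp$setting == "polynomial"], 1e-6)
})

test_that("parameter sweeps anchor at the main model and preserve order", {
  inst <- exp_instance()
  sw <- param_sweep(inst$series, inst$config, "beta", c(0.95, 0.98, 1))
  expect_identical(nrow(sw), 3L)
  expect_true(sw$main[2])
  expect_equal(sw$variation_pct[2], 0)
  anchor <- rrml_fit(inst$series, inst$config)
  expect_equal(sw$rrmad[2], anchor$rrmad)
  expect_equal(sw$variation_pct,
               100 * (sw$rrmad - anchor$rrmad) / anchor$rrmad)
})

test_that("concentrating probability on one scenario collapses the dispersion", {
  inst <- exp_instance()
  s <- inst$series; s$p <- c(0, 1, 0)
  f <- rrml_fit(s, inst$config)
  expect_equal(max(f$sigma_bar), 0)
  # the collapsed problem is the weighted LAD of the middle scenario alone
  s_mid <- scenario_series(inst$series$y[, 2, drop = FALSE],
                           rho = inst$series$rho[2])
  f_mid <- rrml_fit(s_mid, inst$config)
  expect_rel_equal(f$rrmad, f_mid$rrmad, 1e-6)
})

test_that("probability sweep reports both objective and R2 variation", {
  inst <- exp_instance()
  sw <- param_sweep(inst$series, inst$config, "p",
                    list(rep(1, 3) / 3, c(0.25, 0.5, 0.25), c(0, 1, 0)))
  expect_true(all(c("r2_variation_pct", "variation_pct") %in% names(sw)))
  expect_true(sw$main[1])
  expect_equal(sw$variation_pct[1], 0)
  expect_equal(sw$r2_variation_pct[1], 0)
})

test_that("sweeps validate their settings", {
  inst <- exp_instance()
  expect_error(param_sweep(inst$series, inst$config, "p", list(c(0.5, 0.5, 0.5))),
               class = "rrml_invalid")
  expect_error(param_sweep(inst$series, inst$config, "rho", list(c(-1, 1, 1))),
               class = "rrml_invalid")
  expect_error(param_sweep(inst$series, inst$config, "beta", c(0.5, 2)),
               class = "rrml_invalid")
  expect_error(degree_scan(inst$series, inst$config, k_range = 1:3),
               class = "rrml_invalid")
})

test_that("sweeps are deterministic: re-running reproduces the table exactly", {
  inst <- exp_instance()
  a <- param_sweep(inst$series, inst$config, "lambda", c(0, 0.5, 1))
  b <- param_sweep(inst$series, inst$config, "lambda", c(0, 0.5, 1))
  expect_identical(a, b)
})

test_that("sweep tables export rounded and full-precision views", {
  inst <- exp_instance()
  sw <- param_sweep(inst$series, inst$config, "beta", c(0.95, 0.98))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_table(sw, path)
  rounded <- utils::read.csv(path)
  full <- utils::read.csv(sub("\\.csv$", ".full.csv", path))
  expect_identical(rounded$rrmad, round(full$rrmad, 3))
  expect_identical(rounded$variation_pct, round(full$variation_pct, 2))
  expect_equal(full$rrmad, sw$rrmad)
})
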
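# shared fixtures: small random instances with known generating truth

# a random solvable instance plus a matching config; sizes kept small so a
# fit costs well under a second
random_instance <- function(seed, I = NULL, S = NULL, K = NULL,
                            beta = NULL, alpha = NULL, lambda = NULL,
                            noise_sd = NULL) {
  set.seed(seed)
  if (is.null(I)) I <- sample(8:14, 1)
  if (is.null(S)) S <- sample(2:3, 1)
  if (is.null(K)) K <- sample(2:4, 1)
  co <- stats::rnorm(K, 0, 5)
  co[1] <- stats::runif(1, 20, 80)
  sim <- generate_series(I, S, co, noise_kind = "additive",
                         noise_sd = if (is.null(noise_sd)) stats::runif(1, 0.5, 3) else noise_sd,
                         rho = stats::runif(S, 0.7, 1), seed = seed + 5000L)
  cfg <- rrml_config(
    beta = if (is.null(beta)) stats::runif(1, 0.9, 1) else beta,
    alpha = if (is.null(alpha)) stats::runif(1, 0.01, 0.2) else alpha,
    lambda = if (is.null(lambda)) stats::runif(1) else lambda,
    degree = K
  )
  list(series = sim$series, truth = sim$truth, config = cfg)
}

# ordinary least-squares candidate on the resiliency-deflated responses:
# a legitimate competitor coefficient vector, never the optimum of the
# absolute-deviation objective
ols_candidate <- function(series, config) {
  Phi <- basis_matrix(series$x, config)
  I <- nrow(series$y); S <- ncol(series$y)
  qr.solve(Phi[rep(seq_len(I), S), , drop = FALSE],
           as.vector(sweep(series$y, 2, series$rho, "/")))
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected) / (1 + abs(expected)), tol)
}

with_seed_local <- function(seed, code) rrml:::with_local_seed(seed, code)
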
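#' Closed-form model size of the linearized program
#'
#' The LP reformulation has no binary variables, `4 |I| |S|` nonnegative
#' split variables, `2|I| + 3|I||S| + |K| + 1` free variables (trend value,
#' forecast and deviation per cell; mean deviation and dispersion per period;
#' the coefficients; the objective value) and `5|I||S| + 2|I| + 1` equality
#' constraints, so instances grow linearly in the scenario count and the
#' problem stays polynomially solvable at scale.
#'
#' @param n_obs number of observations `|I| >= 1`.
#' @param n_scen number of scenarios `|S| >= 1`.
#' @param n_deg number of basis terms `|K| >= 1`.
#' @return an object of class `rrml_complexity`: a list with `binary`,
#'   `positive`, `free`, `constraints`.
#' @examples
#' complexity_counts(21, 3, 7)  # 0 / 252 / 239 / 358
#' @export
complexity_counts <- function(n_obs, n_scen, n_deg) {
  n_obs <- as.integer(n_obs); n_scen <- as.integer(n_scen); n_deg <- as.integer(n_deg)
  if (anyNA(c(n_obs, n_scen, n_deg)) || n_obs < 1L || n_scen < 1L || n_deg < 1L)
    stop_invalid("all dimensions must be integers >= 1")
  structure(
    list(binary = 0L,
         positive = 4L * n_obs * n_scen,
         free = 2L * n_obs + 3L * n_obs * n_scen + n_deg + 1L,
         constraints = 5L * n_obs * n_scen + 2L * n_obs + 1L),
    class = "rrml_complexity"
  )
}

#' @export
print.rrml_complexity <- function(x, ...) {
  cat(sprintf("binary %d | positive %d | free %d | constraints %d\n",
              x$binary, x$positive, x$free, x$constraints))
  invisible(x)
}

#' Scenario-weighted coefficient of determination
#'
#' Per scenario `s`, `RS_s^2 = 1 - SSE_s / SST_s` with the total sum of
#' squares taken about that scenario's own mean, so a perfect fit gives 1 and
#' predicting the scenario mean gives 0.  The aggregate is the
#' probability-weighted sum `sum_s p_s RS_s^2`; it is at most 1 but is NOT
#' clipped below: badly misspecified fits can push it arbitrarily negative,
#' and masking that would hide a diagnostic.
#'
#' @param y observed `|I| x |S|` matrix.
#' @param y_fit forecast matrix of the same shape.
#' @param p scenario probabilities.
#' @return list with `by_scenario` (length `|S|`) and `aggregate` (scalar).
#' @examples
#' scenario_r2(cbind(1:3), cbind(c(1, 2, 4)), 1)  # RS^2 = 0.5
#' @export
scenario_r2 <- function(y, y_fit, p) {
  y <- as.matrix(y); y_fit <- as.matrix(y_fit)
  if (!all(dim(y) == dim(y_fit)))
    stop_invalid("`y` and `y_fit` must have identical dimensions")
  p <- as.numeric(p)
  if (length(p) != ncol(y))
    stop_invalid("`p` must have one entry per scenario")
  sse <- colSums((y - y_fit)^2)
  sst <- colSums(sweep(y, 2, colMeans(y))^2)
  if (any(sst <= 0)) {
    s <- which(sst <= 0)[1L]
    stop(errorCondition(
      sprintf("R-squared undefined: scenario %d is constant (zero total sum of squares)", s),
      class = c("rrml_undefined_r2", "rrml_invalid", "error")))
  }
  rs <- 1 - sse / sst
  list(by_scenario = unname(rs), aggregate = sum(p * rs))
}

#' Evaluate the RRMAD objective directly at a coefficient vector
#'
#' Computes the forecast, the absolute deviations, their probability-weighted
#' mean and cross-scenario dispersion per period, and returns
#' `beta * sum(w * gamma_bar) + risk_coefficient(alpha, beta) * sum(w * sigma_bar)`
#' straight from the definitions -- no linear program involved.  This is the
#' solver-independent evaluation used to audit every fit.
#'
#' @param a coefficient vector of length `config$degree`.
#' @param series a [scenario_series()].
#' @param config an [rrml_config()].
#' @param parts if `TRUE` return the intermediate quantities as well.
#' @return the objective value, or (with `parts = TRUE`) a list with
#'   `rrmad`, `y_fit`, `gamma`, `gamma_bar`, `sigma_bar`, `weights`.
#' @examples
#' s <- scenario_series(cbind(c(1, 2, 10)), rho = 1)
#' cfg <- rrml_config(beta = 1, degree = 1)
#' rrmad_evaluate(2, s, cfg)  # mean absolute error 3
#' @export
rrmad_evaluate <- function(a, series, config, parts = FALSE) {
  series <- check_series(series)
  config <- check_config(config)
  y_fit <- rrml_forecast(a, series, config)
  gamma <- abs(y_fit - series$y)
  gamma_bar <- drop(gamma %*% series$p)
  sigma_bar <- drop(abs(gamma - gamma_bar) %*% series$p)
  w <- observation_weights(config$lambda, nrow(gamma))
  rrmad <- config$beta * sum(w * gamma_bar) +
    risk_coefficient(config$alpha, config$beta) * sum(w * sigma_bar)
  if (!parts) return(rrmad)
  list(rrmad = rrmad, y_fit = y_fit, gamma = gamma,
       gamma_bar = gamma_bar, sigma_bar = sigma_bar, weights = w)
}
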
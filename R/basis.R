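#' Basis expansion of the regressor
#'
#' All four families are powers of a transformed regressor `g(x)`:
#' polynomial `g(x) = x`; sine type 1 `g(x) = sin(omega x)`; sine type 2
#' `g(x) = x sin(omega x)`; sine type 3 `g(x) = x + sin(omega x)`.  Term `k`
#' is `g(x)^(k-1)`, so the first column is always the constant 1 and each
#' family keeps the fit linear in the coefficients (the model stays an LP).
#'
#' @param x numeric vector of regressor values (already encoded; see
#'   [rrml_config()]'s `x_scale`).
#' @param config an [rrml_config()].
#' @return `basis_matrix()`: a `length(x) x degree` matrix; `basis_row()`:
#'   a numeric vector of length `degree` for a scalar `x`.
#' @examples
#' basis_row(3, rrml_config(degree = 4))          # 1 3 9 27
#' basis_matrix(1:5, rrml_config(degree = 3, basis = "sine3", omega = pi))
#' @export
basis_matrix <- function(x, config) {
  config <- check_config(config)
  x <- as.numeric(x)
  g <- switch(config$basis,
    polynomial = x,
    sine1 = sin(config$omega * x),
    sine2 = x * sin(config$omega * x),
    sine3 = x + sin(config$omega * x)
  )
  outer(g, seq_len(config$degree) - 1, `^`)
}

#' @rdname basis_matrix
#' @export
basis_row <- function(x, config) {
  if (length(x) != 1L) stop_invalid("`x` must be a single value; use basis_matrix() for vectors")
  drop(basis_matrix(x, config))
}

# regressor encoding: counter (stored x), raw calendar labels, or unit scaling
encode_x <- function(series, config) {
  switch(config$x_scale,
    counter = series$x,
    raw = {
      if (is.null(series$labels))
        stop_invalid("x_scale = \"raw\" needs calendar labels on the series")
      lab <- suppressWarnings(as.numeric(series$labels))
      if (anyNA(lab)) stop_invalid("calendar labels are not numeric; cannot use x_scale = \"raw\"")
      lab
    },
    unit = {
      x <- series$x
      if (length(x) == 1L) return(0)
      (x - min(x)) / (max(x) - min(x))
    }
  )
}

#' Scenario forecasts from a coefficient vector
#'
#' Applies the resiliency scaling `y'_is = rho_s * f(x_i)` with
#' `f(x) = sum_k a_k g(x)^(k-1)`.  The forecast is linear in `a` and
#' homogeneous of degree one in `rho`.
#'
#' @param a coefficient vector of length `config$degree`.
#' @param series a [scenario_series()].
#' @param config an [rrml_config()].
#' @return an `|I| x |S|` matrix of forecasts.
#' @examples
#' s <- scenario_series(cbind(c(1, 2, 3)), rho = 1)
#' rrml_forecast(5, s, rrml_config(degree = 1))  # constant 5
#' @export
rrml_forecast <- function(a, series, config) {
  series <- check_series(series)
  config <- check_config(config)
  a <- as.numeric(a)
  if (length(a) != config$degree)
    stop_invalid("`a` must have length %d (config$degree), got %d",
                 config$degree, length(a))
  Phi <- basis_matrix(encode_x(series, config), config)
  f <- drop(Phi %*% a)
  out <- tcrossprod(f, series$rho)
  dimnames(out) <- dimnames(series$y)
  out
}
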
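#' Tuning parameters for an RRMAD fit
#'
#' @param beta conservativity coefficient in `[0, 1]`: weight of the mean
#'   absolute deviation term against the cross-scenario dispersion term.
#'   `beta = 1` drops the dispersion term entirely.
#' @param alpha confidence level in `(0, 1)`: the dispersion term is scaled
#'   by `(1 - beta) * sqrt(-2 * log(alpha))`, so a smaller `alpha` penalizes
#'   error dispersion more heavily.
#' @param lambda old/new-data weight factor in `[0, 1]`: `0` weights the
#'   oldest observations most, `1` the newest, `0.5` is uniform.  See
#'   [observation_weights()].
#' @param omega cycle period (radians per unit of the regressor); required
#'   for the sinusoidal basis families, ignored by the polynomial one.
#' @param basis basis family: `"polynomial"` uses `x^(k-1)`; `"sine1"`
#'   `sin(omega x)^(k-1)`; `"sine2"` `(x sin(omega x))^(k-1)`; `"sine3"`
#'   `(x + sin(omega x))^(k-1)`.
#' @param degree number of basis terms `|K| >= 1` (so `degree = 7` is a
#'   degree-6 polynomial in the usual naming; the first term is the constant).
#' @param x_scale how the regressor is encoded before entering the basis:
#'   `"counter"` (default) uses the observation counter `1..|I|`, `"raw"` the
#'   calendar labels if present (numerically hazardous for high degrees),
#'   `"unit"` min-max scales the counter to `[0, 1]`.
#' @return an object of class `rrml_config`.
#' @examples
#' rrml_config()                      # the "main" reproduction profile
#' rrml_config(basis = "sine3", omega = pi, degree = 4)
#' @seealso [rrml_profile()] for named parameter profiles.
#' @export
rrml_config <- function(beta = 0.98, alpha = 0.05, lambda = 0.5,
                        omega = NULL,
                        basis = c("polynomial", "sine1", "sine2", "sine3"),
                        degree = 7L,
                        x_scale = c("counter", "raw", "unit")) {
  basis <- match.arg(basis)
  x_scale <- match.arg(x_scale)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1)
    stop_invalid("`beta` must be a single number in [0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must be a single number strictly inside (0, 1)")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop_invalid("`lambda` must be a single number in [0, 1]")
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 1L)
    stop_invalid("`degree` must be an integer >= 1")
  if (basis != "polynomial") {
    if (is.null(omega) || !is.numeric(omega) || length(omega) != 1L || !is.finite(omega))
      stop_invalid("`omega` is required (finite scalar) for basis family \"%s\"", basis)
  }
  structure(
    list(beta = beta, alpha = alpha, lambda = lambda, omega = omega,
         basis = basis, degree = degree, x_scale = x_scale),
    class = "rrml_config"
  )
}

#' Named parameter profiles
#'
#' Two profiles ship with the package:
#' \describe{
#'   \item{`"main"`}{`beta = 0.98`, `alpha = 0.05`, `lambda = 0.5`,
#'     polynomial basis, `degree = 7`, counter encoding.  This is the anchor
#'     configuration against which all sensitivity variations are measured.}
#'   \item{`"elicited"`}{`beta = 0.95`, otherwise as `"main"`, with
#'     `omega = 2 * pi / 12` recorded for sinusoidal runs.  The parameter set
#'     as originally elicited from sector managers.}
#' }
#'
#' @param name `"main"` or `"elicited"`.
#' @param ... overrides forwarded to [rrml_config()].
#' @return an `rrml_config`.
#' @examples rrml_profile("main")
#' @export
rrml_profile <- function(name = c("main", "elicited"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    main     = list(beta = 0.98, alpha = 0.05, lambda = 0.5,
                    basis = "polynomial", degree = 7L),
    elicited = list(beta = 0.95, alpha = 0.05, lambda = 0.5,
                    basis = "polynomial", degree = 7L, omega = 2 * pi / 12)
  )
  args <- utils::modifyList(base, list(...))
  do.call(rrml_config, args)
}

#' @export
print.rrml_config <- function(x, ...) {
  cat(sprintf("<rrml_config> basis=%s degree=%d beta=%g alpha=%g lambda=%g%s x_scale=%s\n",
              x$basis, x$degree, x$beta, x$alpha, x$lambda,
              if (is.null(x$omega)) "" else sprintf(" omega=%g", x$omega),
              x$x_scale))
  invisible(x)
}

check_config <- function(config) {
  if (!inherits(config, "rrml_config"))
    stop_invalid("`config` must be an `rrml_config` object")
  config
}

check_series <- function(series) {
  if (!inherits(series, "scenario_series"))
    stop_invalid("`series` must be a `scenario_series` object")
  series
}
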
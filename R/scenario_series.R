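#' Construct a scenario-indexed production series
#'
#' Bundles the observed panel: an observation counter `x` (one entry per
#' period, strictly increasing), an `|I| x |S|` matrix of observed production
#' `y` (one column per scenario), scenario probabilities `p`, per-scenario
#' resiliency coefficients `rho`, and optional calendar labels for display.
#'
#' Internally `x` is a counter (1, 2, ...); calendar years supplied through
#' `labels` are kept for display and are only used as the regressor when a fit
#' is run with `x_scale = "raw"` (see [rrml_config()]).
#'
#' @param y numeric matrix (or data.frame) of observed production,
#'   observations in rows, scenarios in columns.  Production units (e.g.
#'   million tonnes).
#' @param x observation counters; defaults to `1:nrow(y)`.  Must be strictly
#'   increasing.
#' @param p scenario probabilities, length `ncol(y)`, nonnegative, summing to
#'   1 (within 1e-9).  Defaults to uniform.
#' @param rho resiliency coefficients, length `ncol(y)`, strictly positive.
#'   A value below 1 models disruption-reduced capacity for that scenario.
#' @param labels optional per-observation calendar labels (e.g. years).
#' @return an object of class `scenario_series` with fields `x`, `y`, `p`,
#'   `rho`, `labels`.
#' @examples
#' y <- cbind(a = c(10, 11, 12), b = c(11, 12, 13))
#' s <- scenario_series(y, rho = c(0.9, 0.95))
#' s
#' @seealso [read_series()], [generate_series()], [rrml_fit()]
#' @export
scenario_series <- function(y, x = NULL, p = NULL, rho, labels = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y)) stop("`y` must be numeric", call. = FALSE)
  n <- nrow(y)
  S <- ncol(y)
  if (n < 1L || S < 1L) stop("`y` must have at least one row and one column", call. = FALSE)
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
    stop(sprintf("`y` has a missing entry at observation %d, scenario %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(x)) x <- seq_len(n)
  x <- as.numeric(x)
  if (length(x) != n) stop("`x` must have one entry per row of `y`", call. = FALSE)
  if (n > 1L && any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  if (is.null(p)) p <- rep(1 / S, S)
  p <- as.numeric(p)
  if (length(p) != S) stop("`p` must have one entry per scenario", call. = FALSE)
  if (any(p < 0)) stop("scenario probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("scenario probabilities must sum to 1 (got %.12g)", sum(p)), call. = FALSE)
  rho <- as.numeric(rho)
  if (length(rho) == 1L) rho <- rep(rho, S)
  if (length(rho) != S) stop("`rho` must have one entry per scenario", call. = FALSE)
  if (any(rho <= 0)) stop("resiliency coefficients must be strictly positive", call. = FALSE)
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` must have one entry per observation", call. = FALSE)
  structure(
    list(x = x, y = y, p = p, rho = rho, labels = labels),
    class = "scenario_series"
  )
}

#' @export
print.scenario_series <- function(x, ...) {
  cat(sprintf("<scenario_series> %d observations x %d scenarios\n",
              nrow(x$y), ncol(x$y)))
  cat("  p   =", paste(signif(x$p, 4), collapse = ", "), "\n")
  cat("  rho =", paste(signif(x$rho, 4), collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", x$labels[1L], "...", x$labels[length(x$labels)], "\n")
  cat("  y range:", paste(signif(range(x$y), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
as.data.frame.scenario_series <- function(x, ...) {
  d <- data.frame(x = x$x)
  if (!is.null(x$labels)) d$label <- x$labels
  cbind(d, as.data.frame(x$y))
}

#' Number of observations / scenarios of a series
#' @param series a [scenario_series()]
#' @return integer count.
#' @export
n_obs <- function(series) nrow(series$y)

#' @rdname n_obs
#' @export
n_scen <- function(series) ncol(series$y)

#' Evenly-spaced resiliency ladder
#'
#' Convenience generator for the common elicitation pattern where scenario
#' `s` gets resiliency `base + step * (s - 1)`: with the defaults and three
#' scenarios this is 0.85, 0.90, 0.95 (pessimistic to optimistic).
#'
#' @param n_scen number of scenarios.
#' @param base resiliency of the first (most disrupted) scenario.
#' @param step increment per scenario.
#' @return numeric vector of length `n_scen`.
#' @examples rho_ladder(3)
#' @export
rho_ladder <- function(n_scen, base = 0.85, step = 0.05) {
  stopifnot(n_scen >= 1)
  base + step * (seq_len(n_scen) - 1)
}

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("rrml_invalid", "error")))
}
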
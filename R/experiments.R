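#' @title Study drivers: degree scan, basis comparison, parameter sweeps
#' @description Each driver refits the model across a set of settings and
#'   emits a sweep table whose `variation_pct` column measures
#'   `100 * (rrmad - rrmad_anchor) / rrmad_anchor` against an anchor fit (the
#'   unmodified configuration); the anchor row itself shows 0.00.  Rows keep
#'   the requested order, every run is deterministic, and per-row failures
#'   are recorded rather than aborting the scan.
#' @name experiments
NULL

new_sweep_table <- function(df, parameter, anchor_rrmad, anchor_r2 = NA_real_) {
  structure(df, class = c("rrml_sweep", "data.frame"),
            parameter = parameter,
            anchor_rrmad = anchor_rrmad, anchor_r2 = anchor_r2)
}

variation_pct <- function(value, anchor) 100 * (value - anchor) / anchor

fit_quietly <- function(series, config, ...) {
  tryCatch(
    withCallingHandlers(
      rrml_fit(series, config, ...),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    ),
    error = function(e) e
  )
}

# numerical-stability rule for a scan row: the solver must report optimal and
# the basis matrix condition must keep the forward error below the package's
# 1e-6 relative diagnostic tolerance (kappa * eps < 1e-6)
stability_threshold <- function() 1e-6 / .Machine$double.eps

basis_condition <- function(series, config) {
  Phi <- basis_matrix(encode_x(series, config), config)
  kappa(Phi, exact = nrow(Phi) * ncol(Phi) <= 4096)
}

#' Scan the number of basis terms
#'
#' Refits the model for each `K` in `k_range`, recording the coefficients,
#' the objective, the aggregate R-squared and a `feasible` flag that is
#' `FALSE` when the solver fails or the basis matrix is too ill-conditioned
#' for the diagnostics to be certifiable (condition number above
#' `1e-6 / .Machine$double.eps`, about `4.5e9`).  The selected row is the
#' smallest `K` whose objective is within `1e-3` of the best feasible one:
#' extra terms are only accepted if they buy a real objective improvement.
#'
#' @param series a [scenario_series()].
#' @param config an [rrml_config()]; its `degree` is overridden per row.
#' @param k_range integer vector of term counts, each in `[2, n_obs]`.
#' @param ... forwarded to [rrml_fit()].
#' @return an `rrml_sweep` data.frame with one row per `K` (columns
#'   `setting`, `rrmad`, `variation_pct`, `r2`, `feasible`), the coefficient
#'   table as attribute `"coefficients"`, and the selected `K` as attribute
#'   `"selected"`.
#' @examples
#' s <- demo_production_series()
#' degree_scan(s, rrml_profile("main"), k_range = 2:5)
#' @export
degree_scan <- function(series, config = rrml_profile("main"),
                        k_range = 2:8, ...) {
  series <- check_series(series)
  config <- check_config(config)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > n_obs(series)))
    stop_invalid("`k_range` entries must lie in [2, n_obs]")
  rows <- vector("list", length(k_range))
  coefs <- matrix(NA_real_, length(k_range), max(k_range),
                  dimnames = list(NULL, paste0("a", seq_len(max(k_range)))))
  for (idx in seq_along(k_range)) {
    K <- k_range[idx]
    cfg <- config; cfg$degree <- K
    f <- fit_quietly(series, cfg, ...)
    if (inherits(f, "error")) {
      rows[[idx]] <- data.frame(setting = K, rrmad = NA_real_, r2 = NA_real_,
                                feasible = FALSE, note = conditionMessage(f))
    } else {
      stable <- basis_condition(series, cfg) <= stability_threshold()
      rows[[idx]] <- data.frame(setting = K, rrmad = f$rrmad, r2 = f$r2,
                                feasible = stable && f$status == "optimal",
                                note = if (stable) "" else "ill-conditioned basis")
      coefs[idx, seq_len(K)] <- f$a
    }
  }
  df <- do.call(rbind, rows)
  feas <- df$feasible & !is.na(df$rrmad)
  best <- if (any(feas)) min(df$rrmad[feas]) else NA_real_
  selected <- if (any(feas)) min(df$setting[feas & df$rrmad <= best + 1e-3]) else NA_integer_
  df$variation_pct <- variation_pct(df$rrmad, best)
  df <- df[c("setting", "rrmad", "variation_pct", "r2", "feasible", "note")]
  out <- new_sweep_table(df, "degree", best)
  attr(out, "coefficients") <- coefs
  attr(out, "selected") <- selected
  out
}

#' Compare basis families at a fixed number of terms
#'
#' Fits each family with its paired cycle period and reports the objective
#' variation against the polynomial base model.  The default pairings are
#' full-, half- and double-unit cycles for sine types 1-3 respectively
#' (`2*pi`, `4*pi`, `pi` radians per counter step).
#'
#' @param series a [scenario_series()].
#' @param config an [rrml_config()] supplying everything but the family.
#' @param families character vector of basis families; the first is the
#'   comparison anchor.
#' @param omegas cycle period per family (`NA` for the polynomial family).
#' @param ... forwarded to [rrml_fit()].
#' @return an `rrml_sweep` data.frame with columns `setting` (family),
#'   `omega`, `rrmad`, `variation_pct`, `r2`, `feasible`.
#' @examples
#' s <- demo_production_series()
#' compare_basis(s, rrml_profile("main", degree = 4))
#' @export
compare_basis <- function(series, config = rrml_profile("main"),
                          families = c("polynomial", "sine1", "sine2", "sine3"),
                          omegas = c(NA, 2 * pi, 4 * pi, pi), ...) {
  series <- check_series(series)
  config <- check_config(config)
  if (length(families) != length(omegas))
    stop_invalid("`families` and `omegas` must have the same length")
  rows <- vector("list", length(families))
  for (idx in seq_along(families)) {
    cfg <- config
    cfg$basis <- match.arg(families[idx], c("polynomial", "sine1", "sine2", "sine3"))
    cfg$omega <- if (is.na(omegas[idx])) config$omega else omegas[idx]
    if (cfg$basis != "polynomial" && is.null(cfg$omega))
      stop_invalid("family \"%s\" needs an omega", cfg$basis)
    f <- fit_quietly(series, cfg, ...)
    rows[[idx]] <- if (inherits(f, "error"))
      data.frame(setting = families[idx], omega = omegas[idx],
                 rrmad = NA_real_, r2 = NA_real_, feasible = FALSE)
    else
      data.frame(setting = families[idx], omega = omegas[idx],
                 rrmad = f$rrmad, r2 = f$r2, feasible = f$status == "optimal")
  }
  df <- do.call(rbind, rows)
  anchor <- df$rrmad[1L]
  df$variation_pct <- variation_pct(df$rrmad, anchor)
  df <- df[c("setting", "omega", "rrmad", "variation_pct", "r2", "feasible")]
  new_sweep_table(df, "basis", anchor, df$r2[1L])
}

#' One-parameter sensitivity sweep
#'
#' Refits the model for each setting of one parameter, holding everything
#' else at the supplied configuration, and measures the objective variation
#' against the anchor fit of the unmodified `(series, config)`.  For
#' `parameter = "rho"` and `"p"` each setting is a full vector (length
#' `n_scen`); probability settings must be nonnegative and sum to 1.  The
#' row matching the anchor's own value is marked `main`.  The probability
#' sweep also reports the R-squared variation, since reweighting scenarios
#' moves both the objective and the fit quality.
#'
#' @param series a [scenario_series()].
#' @param config an [rrml_config()].
#' @param parameter one of `"beta"`, `"alpha"`, `"lambda"`, `"rho"`, `"p"`.
#' @param settings numeric vector (scalar parameters) or list of numeric
#'   vectors (`"rho"`, `"p"`).  Defaults mirror the study design: beta
#'   0.95-1, alpha 1-5\%, lambda 0-1, whole-vector resiliency shifts, and
#'   probability mass progressively concentrated on the middle scenario.
#' @param ... forwarded to [rrml_fit()].
#' @return an `rrml_sweep` data.frame with columns `setting`, `rrmad`,
#'   `variation_pct`, `r2` (plus `r2_variation_pct` for `"p"`), `feasible`,
#'   `main`.
#' @examples
#' s <- demo_production_series()
#' param_sweep(s, rrml_profile("main"), "beta", c(0.95, 0.98, 1))
#' @export
param_sweep <- function(series, config = rrml_profile("main"),
                        parameter = c("beta", "alpha", "lambda", "rho", "p"),
                        settings = NULL, ...) {
  series <- check_series(series)
  config <- check_config(config)
  parameter <- match.arg(parameter)
  S <- n_scen(series)
  if (is.null(settings)) {
    settings <- switch(parameter,
      beta = c(0.95, 0.96, 0.97, 0.98, 0.99, 1.00),
      alpha = c(0.01, 0.02, 0.03, 0.04, 0.05),
      lambda = c(0, 0.25, 0.5, 0.75, 1),
      rho = lapply(c(-0.15, -0.10, -0.05, 0, 0.05), function(d) series$rho + d),
      p = if (S == 3L) list(rep(1/3, 3), c(.25, .5, .25), c(.125, .75, .125),
                            c(.05, .9, .05), c(0, 1, 0))
          else stop_invalid("default probability settings need 3 scenarios; pass `settings`")
    )
  }
  if (parameter %in% c("rho", "p")) {
    if (!is.list(settings)) settings <- list(settings)
    for (v in settings) {
      if (length(v) != S) stop_invalid("each %s setting must have length %d", parameter, S)
      if (parameter == "p") {
        if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
          stop_invalid("probability settings must be nonnegative and sum to 1")
      } else if (any(v <= 0)) stop_invalid("resiliency settings must be positive")
    }
  } else {
    settings <- as.numeric(settings)
    ok <- switch(parameter,
      beta = all(settings >= 0 & settings <= 1),
      alpha = all(settings > 0 & settings < 1),
      lambda = all(settings >= 0 & settings <= 1))
    if (!ok) stop_invalid("invalid %s settings", parameter)
  }

  anchor <- fit_quietly(series, config, ...)
  if (inherits(anchor, "error")) stop(anchor)
  anchor_value <- switch(parameter,
    beta = config$beta, alpha = config$alpha, lambda = config$lambda,
    rho = series$rho, p = series$p)

  one <- function(setting) {
    cfg <- config; ser <- series
    if (parameter %in% c("beta", "alpha", "lambda")) cfg[[parameter]] <- setting
    else if (parameter == "rho") ser$rho <- setting
    else ser$p <- setting
    is_main <- isTRUE(all.equal(as.numeric(setting), as.numeric(anchor_value),
                                tolerance = 1e-9))
    f <- if (is_main) anchor else fit_quietly(ser, cfg, ...)
    lab <- if (parameter %in% c("rho", "p"))
      paste(format(setting, trim = TRUE), collapse = "/") else format(setting)
    if (inherits(f, "error"))
      data.frame(setting = lab, rrmad = NA_real_, r2 = NA_real_,
                 feasible = FALSE, main = is_main)
    else
      data.frame(setting = lab, rrmad = f$rrmad, r2 = f$r2,
                 feasible = f$status == "optimal", main = is_main)
  }
  df <- do.call(rbind, lapply(settings, one))
  df$variation_pct <- variation_pct(df$rrmad, anchor$rrmad)
  if (parameter == "p")
    df$r2_variation_pct <- variation_pct(df$r2, anchor$r2)
  keep <- c("setting", "rrmad", "variation_pct", "r2",
            if (parameter == "p") "r2_variation_pct", "feasible", "main")
  new_sweep_table(df[keep], parameter, anchor$rrmad, anchor$r2)
}

#' @export
print.rrml_sweep <- function(x, digits_value = 3L, digits_pct = 2L, ...) {
  cat(sprintf("<rrml_sweep> parameter: %s (anchor rrmad %.6g)\n",
              attr(x, "parameter"), attr(x, "anchor_rrmad")))
  print(format_sweep(x, digits_value, digits_pct), row.names = FALSE)
  invisible(x)
}

# display/export rounding: round-half-even via round(), 3 decimals for values,
# 2 for percentages, mirroring the usual reporting precision
format_sweep <- function(x, digits_value = 3L, digits_pct = 2L) {
  d <- as.data.frame(x)
  for (col in intersect(c("rrmad", "r2"), names(d)))
    d[[col]] <- round(d[[col]], digits_value)
  for (col in intersect(c("variation_pct", "r2_variation_pct"), names(d)))
    d[[col]] <- round(d[[col]], digits_pct)
  d
}

#' Write a sweep table to delimited text
#'
#' Writes the display-rounded table (3 decimals for values, 2 for
#' percentages) to `path` and, unless `precision_path` is `NULL`, the
#' full-precision table alongside it for machine consumption.
#'
#' @param x an `rrml_sweep`.
#' @param path output path for the rounded table.
#' @param sep field separator.
#' @param precision_path path for the full-precision companion (default:
#'   `path` with a `.full` inserted before the extension); `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(x, path, sep = ",",
                              precision_path = default_precision_path(path)) {
  utils::write.table(format_sweep(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(precision_path))
    utils::write.table(as.data.frame(x), precision_path, sep = sep,
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_precision_path <- function(path) {
  sub("(\\.[^.]*)?$", ".full\\1", path)
}
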
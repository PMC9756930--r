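#' Read a scenario series from delimited text
#'
#' Two dialects are accepted (comma- or tab-separated, header row required):
#' \describe{
#'   \item{long}{columns `year`, `scenario`, `production`, optionally `p`
#'     and/or `rho` (constant within scenario).}
#'   \item{wide}{a `year` column followed by one numeric column per
#'     scenario.}
#' }
#' Years become calendar labels; the regressor is the observation counter
#' (see [rrml_config()]'s `x_scale` for alternatives).  Ragged long files
#' (scenarios observed in different years) are rejected, as are missing or
#' non-numeric cells -- the error names the offending row and column.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the header), `"long"` or `"wide"`.
#' @param p,rho scenario probabilities / resiliency coefficients; required
#'   unless supplied by sidecar columns (long format only).  `p` defaults to
#'   uniform.
#' @param sep field separator; `NULL` sniffs comma vs tab from the header.
#' @return a [scenario_series()].
#' @seealso [write_series()]
#' @export
read_series <- function(path, format = c("auto", "long", "wide"),
                        p = NULL, rho = NULL, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         strip.white = TRUE)
  names(d) <- tolower(trimws(names(d)))
  if (format == "auto")
    format <- if (all(c("scenario", "production") %in% names(d))) "long" else "wide"

  if (format == "long") {
    need <- c("year", "scenario", "production")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop_invalid("long format needs columns %s; missing: %s",
                   paste(need, collapse = ", "), paste(miss, collapse = ", "))
    d$production <- check_numeric_col(d, "production")
    scen <- unique(d$scenario)
    years <- sort(unique(d$year))
    tab <- table(d$scenario)
    if (length(unique(tab)) != 1L || any(tab != length(years)))
      stop_invalid("ragged long file: scenarios cover different year sets")
    y <- matrix(NA_real_, length(years), length(scen),
                dimnames = list(NULL, as.character(scen)))
    for (rowi in seq_len(nrow(d))) {
      i <- match(d$year[rowi], years); s <- match(d$scenario[rowi], scen)
      if (!is.na(y[i, s]))
        stop_invalid("duplicate cell at year %s, scenario %s", d$year[rowi], d$scenario[rowi])
      y[i, s] <- d$production[rowi]
    }
    if (anyNA(y)) {
      bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
      stop_invalid("missing cell: year %s, scenario %s", years[bad[1L]], scen[bad[2L]])
    }
    if (is.null(p) && "p" %in% names(d))
      p <- vapply(scen, function(s) unique(d$p[d$scenario == s])[1L], numeric(1))
    if (is.null(rho) && "rho" %in% names(d))
      rho <- vapply(scen, function(s) unique(d$rho[d$scenario == s])[1L], numeric(1))
    labels <- years
  } else {
    ycol <- match("year", names(d))
    if (is.na(ycol)) stop_invalid("wide format needs a `year` column")
    if (anyDuplicated(d[[ycol]]))
      stop_invalid("duplicate year %s in wide file", d[[ycol]][anyDuplicated(d[[ycol]])])
    d <- d[order(d[[ycol]]), , drop = FALSE]
    val <- d[-ycol]
    if (!ncol(val)) stop_invalid("wide format needs at least one scenario column")
    for (cn in names(val)) val[[cn]] <- check_numeric_col(val, cn)
    y <- as.matrix(val)
    labels <- d[[ycol]]
  }
  if (is.null(rho))
    stop_invalid("`rho` must be supplied (argument or sidecar column)")
  scenario_series(y, p = p, rho = rho, labels = labels)
}

check_numeric_col <- function(d, col) {
  v <- d[[col]]
  if (is.character(v)) {
    conv <- suppressWarnings(as.numeric(v))
    if (anyNA(conv) && !anyNA(v))
      stop_invalid("non-numeric value \"%s\" in column `%s` (row %d)",
                   v[which(is.na(conv))[1L]], col, which(is.na(conv))[1L])
    v <- conv
  }
  if (anyNA(v))
    stop_invalid("missing value in column `%s` (row %d)", col, which(is.na(v))[1L])
  v
}

#' Write a scenario series to delimited text
#'
#' @param series a [scenario_series()].
#' @param path output path.
#' @param format `"wide"` or `"long"`; both round-trip through
#'   [read_series()].
#' @param sep field separator.
#' @param sidecar include `p` and `rho` columns (long format only).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("wide", "long"),
                         sep = ",", sidecar = FALSE) {
  series <- check_series(series)
  format <- match.arg(format)
  years <- if (is.null(series$labels)) series$x else series$labels
  if (format == "wide") {
    d <- data.frame(year = years)
    cn <- colnames(series$y)
    if (is.null(cn)) cn <- paste0("s", seq_len(ncol(series$y)))
    for (j in seq_along(cn)) d[[cn[j]]] <- series$y[, j]
  } else {
    S <- ncol(series$y)
    cn <- colnames(series$y)
    if (is.null(cn)) cn <- paste0("s", seq_len(S))
    d <- data.frame(
      year = rep(years, S),
      scenario = rep(cn, each = nrow(series$y)),
      production = as.vector(series$y)
    )
    if (sidecar) {
      d$p <- rep(series$p, each = nrow(series$y))
      d$rho <- rep(series$rho, each = nrow(series$y))
    }
  }
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifests: serializable run configuration
#'
#' A manifest is a flat YAML file tying an input file, a parameter profile
#' with overrides, scenario probabilities and resiliency coefficients, and
#' an output directory into one reproducible run: the same manifest always
#' produces identical outputs.
#'
#' @param input path to a delimited series file (see [read_series()]).
#' @param output_dir directory for outputs (created if missing).
#' @param profile base profile name for [rrml_profile()].
#' @param overrides named list of [rrml_config()] overrides.
#' @param p,rho scenario probabilities / resiliency coefficients.
#' @param backend solver backend identifier (only `"simplex"` ships).
#' @return an object of class `rrml_manifest`.
#' @export
run_manifest <- function(input, output_dir, profile = "main",
                         overrides = list(), p = NULL, rho = NULL,
                         backend = "simplex") {
  structure(list(input = input, output_dir = output_dir, profile = profile,
                 overrides = overrides, p = p, rho = rho, backend = backend),
            class = "rrml_manifest")
}

#' @rdname run_manifest
#' @param manifest an `rrml_manifest` or a path to a YAML manifest.
#' @param path file path for [write_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  do.call(run_manifest, m[intersect(names(m), names(formals(run_manifest)))])
}

#' @rdname run_manifest
#' @details [execute_manifest()] reads the series, fits under the resolved
#'   configuration, and writes `coefficients.txt` (flat key-value
#'   diagnostics) and `fitted.csv` into `output_dir`.  Returns the fit.
#' @export
execute_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (manifest$backend != "simplex")
    stop_invalid("unknown backend \"%s\"", manifest$backend)
  series <- read_series(manifest$input, p = manifest$p, rho = manifest$rho)
  config <- do.call(rrml_profile, c(list(name = manifest$profile), manifest$overrides))
  fit <- rrml_fit(series, config)
  dir.create(manifest$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit(fit, manifest$output_dir)
  fit
}

# flat key-value diagnostics + fitted values table
write_fit <- function(fit, dir) {
  kv <- c(sprintf("rrmad %.15g", fit$rrmad),
          sprintf("r2 %.15g", fit$r2),
          sprintf("tightness_gap %.15g", fit$tightness_gap),
          sprintf("status %s", fit$status),
          sprintf("a%d %.15g", seq_along(fit$a), fit$a),
          sprintf("r2_s%d %.15g", seq_along(fit$r2_by_scenario), fit$r2_by_scenario))
  writeLines(kv, file.path(dir, "coefficients.txt"))
  d <- data.frame(x = fit$series$x)
  if (!is.null(fit$series$labels)) d$label <- fit$series$labels
  colnames(fit$y_fit) <- paste0("fit_", seq_len(ncol(fit$y_fit)))
  utils::write.table(cbind(d, fit$y_fit), file.path(dir, "fitted.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
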
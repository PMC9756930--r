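#' Construct a solver-agnostic equality-form linear program
#'
#' A minimal container: minimize `objective %*% z` subject to `A %*% z = rhs`
#' with `z_j >= 0` where `lower[j] == 0` and `z_j` free where
#' `lower[j] == -Inf`.  [build_lp()] produces these; tests may construct them
#' directly to probe the solver.
#'
#' @param A constraint matrix (rows = equality constraints).
#' @param rhs right-hand side vector.
#' @param objective cost vector (minimization).
#' @param lower per-variable lower bound, each `0` or `-Inf`.
#' @param vars optional data.frame describing the variables (`name`, `role`).
#' @return an object of class `rrml_lp`.
#' @seealso [build_lp()], [solve_lp()], [write_mps()]
#' @export
linear_program <- function(A, rhs, objective, lower = rep(0, ncol(A)), vars = NULL) {
  A <- as.matrix(A)
  if (length(rhs) != nrow(A)) stop_invalid("`rhs` length must equal nrow(A)")
  if (length(objective) != ncol(A)) stop_invalid("`objective` length must equal ncol(A)")
  if (length(lower) != ncol(A)) stop_invalid("`lower` length must equal ncol(A)")
  if (!all(lower %in% c(0, -Inf))) stop_invalid("lower bounds must be 0 or -Inf")
  if (is.null(vars))
    vars <- data.frame(name = paste0("z", seq_len(ncol(A))),
                       role = "generic", stringsAsFactors = FALSE)
  structure(list(A = A, rhs = as.numeric(rhs), objective = as.numeric(objective),
                 lower = as.numeric(lower), vars = vars),
            class = "rrml_lp")
}

#' @export
print.rrml_lp <- function(x, ...) {
  cat(sprintf("<rrml_lp> %d constraints, %d variables (%d nonnegative, %d free)\n",
              nrow(x$A), ncol(x$A), sum(x$lower == 0), sum(!is.finite(x$lower))))
  invisible(x)
}

#' Build the linearized RRMAD program for a series and configuration
#'
#' Lays out, per observation `i` and scenario `s`: free variables for the
#' trend value `f_is`, the forecast `y'_is`, the absolute deviation
#' `gamma_is`, the period mean deviation `gamma_bar_i`, the period dispersion
#' `sigma_bar_i`, the coefficients `a_k` and the objective value `rrmad`;
#' plus the four nonnegative split pairs `va/vb` (for `|y' - y|`) and
#' `va2/vb2` (for `|gamma - gamma_bar|`).  Equality rows encode the basis
#' expansion, the resiliency scaling, both absolute-value splittings, the
#' probability-weighted mean and dispersion definitions, and the objective
#' accounting row; the single cost entry sits on `rrmad`.  Observation
#' weights enter as constants.  The registry always matches
#' [complexity_counts()] for the same dimensions.
#'
#' @param series a [scenario_series()].
#' @param config an [rrml_config()].
#' @param precondition orthonormalize the basis columns (QR) inside the
#'   program and record the triangular factor so coefficients can be mapped
#'   back.  This is a pure change of coefficient variables: the feasible set,
#'   the optimum and all counts are unchanged, but high-degree bases (whose
#'   raw columns span many orders of magnitude) become numerically benign.
#'   Disabled automatically when the basis matrix is rank-deficient or has
#'   more terms than observations.
#' @return an `rrml_lp` (subclass `rrml_rrmad_lp`) carrying the variable
#'   registry, the complexity counts, the basis transform and fit metadata.
#' @examples
#' s <- generate_series(n_obs = 6, n_scen = 2, coefficients = c(10, 1), seed = 1)
#' lp <- build_lp(s$series, rrml_config(degree = 2))
#' lp$counts
#' @export
build_lp <- function(series, config, precondition = TRUE) {
  series <- check_series(series)
  config <- check_config(config)
  I <- nrow(series$y); S <- ncol(series$y); K <- config$degree
  if (I < K)
    message(sprintf("note: %d basis terms with only %d observations; the fit can interpolate", K, I))
  Phi_raw <- basis_matrix(encode_x(series, config), config)
  transform <- NULL
  Phi <- Phi_raw
  if (precondition && I >= K) {
    qrd <- qr(Phi_raw)
    if (qrd$rank == K) {
      Phi <- qr.Q(qrd)
      transform <- qr.R(qrd)   # raw coefficients a = solve(transform, a_lp)
    }
  }
  w <- observation_weights(config$lambda, I)
  rc <- risk_coefficient(config$alpha, config$beta)

  cell <- function(i, s) (s - 1L) * I + i  # column-major cell index in 1..I*S
  IS <- I * S
  # variable layout (free block first, then the nonnegative split block)
  off_a     <- 0L                       # a_k                k = 1..K
  off_f     <- K                        # f_is               IS
  off_yfit  <- K + IS                   # y'_is              IS
  off_gam   <- K + 2L * IS              # gamma_is           IS
  off_gbar  <- K + 3L * IS              # gamma_bar_i        I
  off_sbar  <- K + 3L * IS + I          # sigma_bar_i        I
  off_obj   <- K + 3L * IS + 2L * I     # rrmad              1
  n_free    <- off_obj + 1L
  off_va    <- n_free                   # va_is              IS
  off_vb    <- n_free + IS
  off_va2   <- n_free + 2L * IS
  off_vb2   <- n_free + 3L * IS
  n_var     <- n_free + 4L * IS

  grid <- expand.grid(i = seq_len(I), s = seq_len(S))
  nm <- character(n_var)
  nm[off_a + seq_len(K)] <- paste0("a", seq_len(K))
  nm[off_f + seq_len(IS)]    <- sprintf("f[%d,%d]", grid$i, grid$s)
  nm[off_yfit + seq_len(IS)] <- sprintf("yfit[%d,%d]", grid$i, grid$s)
  nm[off_gam + seq_len(IS)]  <- sprintf("gamma[%d,%d]", grid$i, grid$s)
  nm[off_gbar + seq_len(I)]  <- sprintf("gamma_bar[%d]", seq_len(I))
  nm[off_sbar + seq_len(I)]  <- sprintf("sigma_bar[%d]", seq_len(I))
  nm[off_obj + 1L] <- "rrmad"
  nm[off_va + seq_len(IS)]  <- sprintf("va[%d,%d]", grid$i, grid$s)
  nm[off_vb + seq_len(IS)]  <- sprintf("vb[%d,%d]", grid$i, grid$s)
  nm[off_va2 + seq_len(IS)] <- sprintf("va2[%d,%d]", grid$i, grid$s)
  nm[off_vb2 + seq_len(IS)] <- sprintf("vb2[%d,%d]", grid$i, grid$s)
  role <- c(rep("coefficient", K), rep("trend", IS), rep("forecast", IS),
            rep("deviation", IS), rep("mean_deviation", I), rep("dispersion", I),
            "objective",
            rep("split_va", IS), rep("split_vb", IS),
            rep("split_va2", IS), rep("split_vb2", IS))

  m <- 5L * IS + 2L * I + 1L
  A <- matrix(0, m, n_var)
  rhs <- numeric(m)
  r <- 0L
  for (s in seq_len(S)) for (i in seq_len(I)) {
    cs <- cell(i, s)
    # basis expansion: f_is - sum_k a_k phi_k(x_i) = 0
    r <- r + 1L; A[r, off_f + cs] <- 1; A[r, off_a + seq_len(K)] <- -Phi[i, ]
    # resiliency scaling: y'_is - rho_s f_is = 0
    r <- r + 1L; A[r, off_yfit + cs] <- 1; A[r, off_f + cs] <- -series$rho[s]
    # deviation split: gamma_is - va_is - vb_is = 0
    r <- r + 1L; A[r, off_gam + cs] <- 1; A[r, off_va + cs] <- -1; A[r, off_vb + cs] <- -1
    # signed residual: y'_is - va_is + vb_is = y_is
    r <- r + 1L; A[r, off_yfit + cs] <- 1; A[r, off_va + cs] <- -1; A[r, off_vb + cs] <- 1
    rhs[r] <- series$y[i, s]
    # dispersion split: gamma_is - gamma_bar_i - va2_is + vb2_is = 0
    r <- r + 1L; A[r, off_gam + cs] <- 1; A[r, off_gbar + i] <- -1
    A[r, off_va2 + cs] <- -1; A[r, off_vb2 + cs] <- 1
  }
  for (i in seq_len(I)) {
    # mean deviation: gamma_bar_i - sum_s p_s gamma_is = 0
    r <- r + 1L; A[r, off_gbar + i] <- 1
    A[r, off_gam + cell(i, seq_len(S))] <- -series$p
    # dispersion: sigma_bar_i - sum_s p_s (va2_is + vb2_is) = 0
    r <- r + 1L; A[r, off_sbar + i] <- 1
    A[r, off_va2 + cell(i, seq_len(S))] <- -series$p
    A[r, off_vb2 + cell(i, seq_len(S))] <- -series$p
  }
  # objective accounting: rrmad - beta sum_i w_i gamma_bar_i - rc sum_i w_i sigma_bar_i = 0
  r <- r + 1L
  A[r, off_obj + 1L] <- 1
  A[r, off_gbar + seq_len(I)] <- -config$beta * w
  A[r, off_sbar + seq_len(I)] <- -rc * w
  stopifnot(r == m)

  objective <- numeric(n_var)
  objective[off_obj + 1L] <- 1
  lower <- c(rep(-Inf, n_free), rep(0, 4L * IS))

  lp <- linear_program(A, rhs, objective, lower,
                       vars = data.frame(name = nm, role = role,
                                         stringsAsFactors = FALSE))
  lp$counts <- list(binary = 0L, positive = sum(lower == 0),
                    free = sum(!is.finite(lower)), constraints = m)
  lp$index <- list(a = off_a + seq_len(K), f = off_f + seq_len(IS),
                   yfit = off_yfit + seq_len(IS), gamma = off_gam + seq_len(IS),
                   gamma_bar = off_gbar + seq_len(I), sigma_bar = off_sbar + seq_len(I),
                   rrmad = off_obj + 1L,
                   va = off_va + seq_len(IS), vb = off_vb + seq_len(IS),
                   va2 = off_va2 + seq_len(IS), vb2 = off_vb2 + seq_len(IS))
  lp$dims <- c(I = I, S = S, K = K)
  lp$basis_transform <- transform
  lp$meta <- list(weights = w, risk = rc, config = config, series = series)
  class(lp) <- c("rrml_rrmad_lp", class(lp))
  lp
}

#' Export a linear program in MPS format
#'
#' Writes the equality-form program in the standard (free-form) MPS layout so
#' an instance can be loaded into any external LP solver for cross-checking.
#' Free variables are declared with `FR` bound lines.
#'
#' @param lp an `rrml_lp`.
#' @param path output file path.
#' @param name problem name stamped in the header.
#' @return `path`, invisibly.
#' @export
write_mps <- function(lp, path, name = "RRML") {
  if (!inherits(lp, "rrml_lp")) stop_invalid("`lp` must be an `rrml_lp`")
  n <- ncol(lp$A)
  vn <- sprintf("X%06d", seq_len(n))
  rn <- sprintf("R%06d", seq_len(nrow(lp$A)))
  out <- c(sprintf("NAME          %s", name), "ROWS", " N  COST",
           sprintf(" E  %s", rn), "COLUMNS")
  for (j in seq_len(n)) {
    rows <- which(lp$A[, j] != 0)
    ent <- sprintf("    %-10s%-10s%.15g", vn[j], rn[rows], lp$A[rows, j])
    if (lp$objective[j] != 0)
      ent <- c(sprintf("    %-10s%-10s%.15g", vn[j], "COST", lp$objective[j]), ent)
    out <- c(out, ent)
  }
  out <- c(out, "RHS")
  nz <- which(lp$rhs != 0)
  out <- c(out, sprintf("    %-10s%-10s%.15g", "RHS1", rn[nz], lp$rhs[nz]))
  out <- c(out, "BOUNDS")
  fr <- which(!is.finite(lp$lower))
  if (length(fr)) out <- c(out, sprintf(" FR %-10s%s", "BND1", vn[fr]))
  out <- c(out, "ENDATA")
  writeLines(out, path)
  invisible(path)
}
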
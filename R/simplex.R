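#' Solve an equality-form linear program
#'
#' A dense two-phase revised simplex.  Free variables are split into
#' difference pairs internally; phase 1 starts from an artificial basis and
#' certifies feasibility, phase 2 optimizes with artificial columns barred
#' from re-entering.  The basis inverse is maintained by elementary row
#' updates and refactorized periodically; a Dantzig pricing rule falls back
#' to Bland's rule after prolonged degeneracy so termination is guaranteed.
#' The returned point is a vertex solution; LAD-type programs can have
#' multiple optima, and only the objective value is unique.
#'
#' @param lp an [linear_program()] / [build_lp()] object.
#' @param tol pivot/optimality tolerance (relative).
#' @param maxit iteration cap; defaults to `200 * (m + n)`.
#' @return a list with `solution` (in the original variable space),
#'   `objective`, `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"numerically-failed"`) and `iterations`.  Never reports a non-optimal
#'   point as `"optimal"`.
#' @examples
#' lp <- linear_program(A = rbind(c(1, 1)), rhs = 2, objective = c(1, 2))
#' solve_lp(lp)$solution  # (2, 0)
#' @export
solve_lp <- function(lp, tol = 1e-9, maxit = NULL) {
  if (!inherits(lp, "rrml_lp")) stop_invalid("`lp` must be an `rrml_lp`")
  A <- lp$A; b <- lp$rhs; cost <- lp$objective
  m <- nrow(A); n <- ncol(A)
  free <- which(!is.finite(lp$lower))
  As <- cbind(A, -A[, free, drop = FALSE])
  cs <- c(cost, -cost[free])
  N <- ncol(As)
  neg <- b < 0
  if (any(neg)) { As[neg, ] <- -As[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  if (is.null(maxit)) maxit <- max(20000L, 200L * (m + N))

  # max-norm equilibration (two passes): high-degree basis columns can span
  # many orders of magnitude, which otherwise poisons pivot tolerances
  rscl <- rep(1, m); cscl <- rep(1, N)
  for (pass in 1:2) {
    rmax <- apply(abs(As), 1L, max); rmax[rmax == 0] <- 1
    As <- As / rmax; rscl <- rscl * rmax
    cmax <- apply(abs(As), 2L, max); cmax[cmax == 0] <- 1
    As <- sweep(As, 2L, cmax, `/`); cscl <- cscl * cmax
  }
  b <- b / rscl
  cs <- cs / cscl
  bscale <- 1 + max(abs(b))

  Aall <- cbind(As, diag(m))
  art <- N + seq_len(m)

  # phase 1: minimize the artificial sum
  ph1 <- simplex_core(Aall, b, cost = c(rep(0, N), rep(1, m)),
                      basis = art, Binv = diag(m), xB = b,
                      barred = rep(FALSE, N + m), tol = tol, maxit = maxit)
  fail <- function(st) list(solution = rep(NA_real_, n), objective = NA_real_,
                            status = st, iterations = ph1$iter)
  if (ph1$status == "maxit") return(fail("numerically-failed"))
  infeas <- sum(ph1$xB[ph1$basis > N])
  if (infeas > 1e-7 * bscale) return(fail("infeasible"))

  basis <- ph1$basis; Binv <- ph1$Binv; xB <- ph1$xB
  # pivot residual artificials out of the basis where a structural column can
  # replace them; rows where none can are redundant and stay inert
  for (r in which(basis > N)) {
    v <- drop(Binv[r, , drop = FALSE] %*% As)
    v[basis[basis <= N]] <- 0
    j <- which.max(abs(v))
    if (abs(v[j]) > 1e-7) {
      wcol <- drop(Binv %*% Aall[, j])
      Brow <- Binv[r, ] / wcol[r]
      Binv <- Binv - outer(wcol, Brow)
      Binv[r, ] <- Brow
      basis[r] <- j
      xB <- drop(Binv %*% b)
      xB[xB < 0] <- 0
    }
  }

  # phase 2: artificial columns barred from entering
  ph2 <- simplex_core(Aall, b, cost = c(cs, rep(0, m)),
                      basis = basis, Binv = Binv, xB = xB,
                      barred = c(rep(FALSE, N), rep(TRUE, m)),
                      tol = tol, maxit = maxit)
  if (ph2$status == "maxit")
    return(list(solution = rep(NA_real_, n), objective = NA_real_,
                status = "numerically-failed", iterations = ph1$iter + ph2$iter))
  if (ph2$status == "unbounded")
    return(list(solution = rep(NA_real_, n), objective = -Inf,
                status = "unbounded", iterations = ph1$iter + ph2$iter))

  z <- numeric(N + m)
  z[ph2$basis] <- ph2$xB
  z[seq_len(N)] <- z[seq_len(N)] / cscl
  x <- z[seq_len(n)]
  x[free] <- x[free] - z[n + seq_along(free)]
  list(solution = x, objective = sum(cost * x), status = "optimal",
       iterations = ph1$iter + ph2$iter)
}

# revised simplex inner loop on min cost'z, Acols z = b, z >= 0,
# starting from a feasible basis with inverse Binv and values xB
simplex_core <- function(Acols, b, cost, basis, Binv, xB, barred, tol, maxit) {
  m <- nrow(Acols)
  cscale <- 1 + max(abs(cost))
  iter <- 0L; degen <- 0L; bland <- FALSE
  repeat {
    if (iter >= maxit)
      return(list(status = "maxit", basis = basis, Binv = Binv, xB = xB, iter = iter))
    if (iter > 0L && iter %% 150L == 0L) {
      Bf <- tryCatch(solve(Acols[, basis, drop = FALSE]), error = function(e) NULL)
      if (!is.null(Bf)) {
        Binv <- Bf
        xB <- drop(Binv %*% b)
        xB[xB < 0 & xB > -1e-9 * (1 + max(abs(b)))] <- 0
      }
    }
    d <- cost - drop(crossprod(Acols, crossprod(Binv, cost[basis])))
    d[basis] <- 0
    d[barred] <- Inf
    if (bland) {
      cand <- which(d < -tol * cscale)
      if (!length(cand))
        return(list(status = "optimal", basis = basis, Binv = Binv, xB = xB, iter = iter))
      j <- cand[1L]
    } else {
      j <- which.min(d)
      if (d[j] >= -tol * cscale)
        return(list(status = "optimal", basis = basis, Binv = Binv, xB = xB, iter = iter))
    }
    w <- drop(Binv %*% Acols[, j])
    pos <- which(w > tol)
    if (!length(pos))
      return(list(status = "unbounded", basis = basis, Binv = Binv, xB = xB, iter = iter))
    ratios <- xB[pos] / w[pos]
    theta <- min(ratios)
    tie <- pos[ratios <= theta + tol * (1 + abs(theta))]
    r <- if (bland) tie[which.min(basis[tie])] else tie[which.max(w[tie])]
    theta <- xB[r] / w[r]
    degen <- if (theta <= tol) degen + 1L else 0L
    if (degen > 2L * m + 200L) bland <- TRUE
    xB <- xB - theta * w
    xB[r] <- theta
    xB[xB < 0] <- 0
    Brow <- Binv[r, ] / w[r]
    Binv <- Binv - outer(w, Brow)
    Binv[r, ] <- Brow
    basis[r] <- j
    iter <- iter + 1L
  }
}
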
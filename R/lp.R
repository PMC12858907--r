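#' Solve a bounded linear program with equality constraints
#'
#' Maximizes (or minimizes) \code{obj \%*\% x} subject to \code{A \%*\% x = b}
#' and \code{lb <= x <= ub}, the canonical form of every flux balance problem
#' in this package. A two-phase primal simplex with explicit variable bounds
#' is used: upper bounds are handled inside the ratio test (bound flips), so
#' no slack columns are added, and degenerate bases are resolved with Bland's
#' rule, which makes the pivot sequence -- and therefore the returned vertex
#' -- deterministic for identical inputs.
#'
#' Lower bounds must be finite; upper bounds may be \code{Inf}.
#'
#' @param obj numeric objective coefficients, length \code{ncol(A)}.
#' @param A constraint matrix (dense or \code{Matrix} sparse), equalities only.
#' @param b right-hand side, length \code{nrow(A)}.
#' @param lb,ub variable bounds; \code{lb} finite, \code{ub} may be \code{Inf}.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot / feasibility tolerance.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{x} (solution, \code{NULL} unless optimal) and \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("lp_solve: lower bounds must be finite")
  if (any(ub < lb)) return(list(status = "infeasible", x = NULL, objective = NA_real_))
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## shift to y = x - lb, 0 <= y <= s
  s <- ub - lb
  b2 <- as.numeric(b) - as.vector(A %*% lb)
  neg <- b2 < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b2[neg] <- -b2[neg]
  }

  ## phase 1: artificial column per row, minimize their sum
  nt <- n + m
  A0 <- cbind(A, diag(m))                 # kept for the final refinement solve
  Tm <- A0
  sfull <- c(s, rep(Inf, m))
  basis <- n + seq_len(m)
  xB <- b2
  atupper <- rep(FALSE, nt)
  c1 <- c(rep(0, n), rep(-1, m))

  st <- simplex_iterate(Tm, xB, basis, atupper, c1, sfull, tol)
  if (st$status != "optimal")
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  art_val <- sum(vapply(seq_len(m), function(i) {
    j <- st$basis[i]
    if (j > n) st$xB[i] else 0
  }, numeric(1)))
  scale <- max(1, max(abs(b2)))
  if (art_val > 1e-7 * scale)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  ## pin artificials to zero and run phase 2 on the original objective
  sfull[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  st2 <- simplex_iterate(st$Tm, st$xB, st$basis, st$atupper, c2, sfull, tol)
  if (st2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = Inf))
  if (st2$status != "optimal")
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  ## refine: recompute the basic values from the original system so that
  ## accumulated pivot round-off does not leak into reported fluxes
  yfull <- numeric(nt)
  nb_up <- st2$atupper & is.finite(sfull)
  nb_up[st2$basis] <- FALSE
  yfull[nb_up] <- sfull[nb_up]
  rhs <- b2 - as.vector(A0 %*% yfull)
  B <- A0[, st2$basis, drop = FALSE]
  yB <- tryCatch(solve(qr(B, LAPACK = TRUE), rhs), error = function(e) NULL)
  if (is.null(yB) || any(!is.finite(yB)) ||
      max(abs(yB - st2$xB)) > 1e-4 * max(1, max(abs(st2$xB)))) {
    yB <- st2$xB                          # refinement rejected, keep iterate
  }
  yfull[st2$basis] <- yB
  y <- yfull[seq_len(n)]
  x <- pmin(pmax(y + lb, lb), ub)         # clip residual round-off
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}

## One run of the bounded-variable primal simplex on an explicit tableau.
## Tm is B^-1 A (m x nt), xB the basic values, basis the basic column index
## per row, atupper the nonbasic-at-upper flags, cc the objective (maximized),
## s the upper bounds of the shifted variables. Dantzig pricing is used until
## the iteration count suggests stalling, then Bland's rule guarantees
## termination.
simplex_iterate <- function(Tm, xB, basis, atupper, cc, s, tol) {
  m <- nrow(Tm); nt <- ncol(Tm)
  maxit <- 200L * (m + nt) + 2000L
  bland_after <- 10L * (m + nt) + 200L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("lp_solve: iteration limit exceeded")
    use_bland <- it > bland_after

    cB <- cc[basis]
    d <- cc - as.vector(crossprod(cB, Tm))
    is_basic <- logical(nt); is_basic[basis] <- TRUE
    elig_lo <- !is_basic & !atupper & d > tol
    elig_up <- !is_basic & atupper & d < -tol
    elig <- which(elig_lo | elig_up)
    if (!length(elig))
      return(list(status = "optimal", Tm = Tm, xB = xB, basis = basis,
                  atupper = atupper))
    e <- if (use_bland) elig[1L] else elig[which.max(abs(d[elig]))]
    sigma <- if (atupper[e]) -1 else 1    # direction of y_e

    w <- Tm[, e]
    delta <- sigma * w                    # xB changes by -delta * t
    tmax <- s[e]                          # own bound flip distance
    tbest <- tmax; leave_r <- 0L; leave_hits_upper <- FALSE
    for (i in seq_len(m)) {
      di <- delta[i]
      if (di > tol) {
        ti <- xB[i] / di
        if (ti < tbest - 1e-12 ||
            (leave_r > 0L && ti < tbest + 1e-12 && use_bland &&
             basis[i] < basis[leave_r])) {
          tbest <- ti; leave_r <- i; leave_hits_upper <- FALSE
        }
      } else if (di < -tol) {
        ui <- s[basis[i]]
        if (is.finite(ui)) {
          ti <- (ui - xB[i]) / (-di)
          if (ti < tbest - 1e-12 ||
              (leave_r > 0L && ti < tbest + 1e-12 && use_bland &&
               basis[i] < basis[leave_r])) {
            tbest <- ti; leave_r <- i; leave_hits_upper <- TRUE
          }
        }
      }
    }
    if (!is.finite(tbest))
      return(list(status = "unbounded", Tm = Tm, xB = xB, basis = basis,
                  atupper = atupper))
    tbest <- max(tbest, 0)

    if (leave_r == 0L) {                  # bound flip, basis unchanged
      xB <- xB - delta * tbest
      atupper[e] <- !atupper[e]
      next
    }

    ## pivot: e enters on row leave_r, basis[leave_r] leaves
    enter_val <- if (atupper[e]) s[e] - tbest else tbest
    xB <- xB - delta * tbest
    l <- basis[leave_r]
    piv <- Tm[leave_r, e]
    Tr <- Tm[leave_r, ] / piv
    colv <- Tm[, e]
    Tm <- Tm - outer(colv, Tr)
    Tm[leave_r, ] <- Tr
    xB[leave_r] <- enter_val
    basis[leave_r] <- e
    atupper[l] <- leave_hits_upper
    atupper[e] <- FALSE
  }
}
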
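# Dense two-phase primal simplex.
#
# All LPs in this package are small (tens to a few hundred variables), dense
# enough that a tableau method is adequate, and frequently degenerate (the
# steady-state rows S v = 0 have zero right-hand sides).  The implementation
# uses the classical two-phase full-tableau simplex with a Dantzig entering
# rule and an automatic switch to Bland's rule when progress stalls, which
# guarantees termination on degenerate problems.

#' Solve a linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to equality constraints
#' \code{Aeq x = beq}, inequality constraints \code{Ale x <= ble} and variable
#' bounds \code{lb <= x <= ub}.
#'
#' @param obj numeric objective coefficient vector.
#' @param Aeq,beq equality constraint matrix and right-hand side (may be
#'   \code{NULL}).
#' @param Ale,ble inequality (\code{<=}) constraint matrix and right-hand side
#'   (may be \code{NULL}).
#' @param lb,ub variable bounds, recycled to the number of variables.
#'   Infinite bounds are capped at a large finite value.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivoting tolerance.
#' @return a list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}), \code{objective} and \code{x}.
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     lb = 0, ub = Inf, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  BIG <- 1e7
  lb[!is.finite(lb)] <- -BIG
  ub[!is.finite(ub)] <- BIG

  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # shift to y = x - lb >= 0
  Aeq <- if (is.null(Aeq) || NROW(Aeq) == 0L) matrix(0, 0, n) else
    matrix(as.numeric(Aeq), ncol = n)
  Ale <- if (is.null(Ale) || NROW(Ale) == 0L) matrix(0, 0, n) else
    matrix(as.numeric(Ale), ncol = n)
  beq <- if (nrow(Aeq)) as.numeric(beq) - drop(Aeq %*% lb) else numeric(0)
  ble <- if (nrow(Ale)) as.numeric(ble) - drop(Ale %*% lb) else numeric(0)
  if (length(ble) && any(!is.finite(ble))) {
    keep <- is.finite(ble)
    Ale <- Ale[keep, , drop = FALSE]
    ble <- ble[keep]
  }

  # upper bounds become explicit rows y_j <= ub_j - lb_j
  span <- ub - lb
  bnd <- which(span < BIG * 1.5)
  if (length(bnd)) {
    Aub <- matrix(0, length(bnd), n)
    Aub[cbind(seq_along(bnd), bnd)] <- 1
    Ale <- rbind(Ale, Aub)
    ble <- c(ble, span[bnd])
  }

  res <- simplex_two_phase(cc, Aeq, beq, Ale, ble, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# Standard-form solver: min c'y s.t. Ale y <= ble, Aeq y = beq, y >= 0.
simplex_two_phase <- function(cc, Aeq, beq, Ale, ble, tol = 1e-9) {
  n <- length(cc)
  m1 <- nrow(Ale)
  m2 <- nrow(Aeq)
  m <- m1 + m2
  if (m == 0L) return(list(status = "optimal", x = rep(0, n)))

  A <- rbind(Ale, Aeq)
  b <- c(ble, beq)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # slack/surplus columns for the inequality rows
  Sl <- matrix(0, m, m1)
  if (m1) Sl[cbind(seq_len(m1), seq_len(m1))] <- ifelse(flip[seq_len(m1)], -1, 1)

  # artificials wherever the slack cannot start basic
  need_art <- c(flip[seq_len(m1)], rep(TRUE, m2))
  art_rows <- which(need_art)
  n_art <- length(art_rows)
  Ar <- matrix(0, m, n_art)
  if (n_art) Ar[cbind(art_rows, seq_len(n_art))] <- 1

  Tmat <- cbind(A, Sl, Ar)
  ntot <- ncol(Tmat)
  n_real <- n + m1
  basis <- integer(m)
  basis[!need_art] <- n + which(!need_art)
  basis[need_art] <- n_real + seq_len(n_art)
  art_cols <- if (n_art) (n_real + 1L):ntot else integer(0)

  if (n_art) {
    c1 <- c(rep(0, n_real), rep(1, n_art))
    ph1 <- simplex_core(Tmat, b, c1, basis, allowed = rep(TRUE, ntot), tol = tol)
    if (ph1$status != "optimal" || ph1$value > 1e-7) {
      return(list(status = "infeasible", x = NULL))
    }
    Tmat <- ph1$Tmat; b <- ph1$b; basis <- ph1$basis
    # drive residual zero-level artificials out of the basis where possible
    for (r in which(basis %in% art_cols)) {
      elig <- which(abs(Tmat[r, seq_len(n_real)]) > 1e-8)
      elig <- setdiff(elig, basis)
      if (length(elig)) {
        j <- elig[1L]
        pv <- Tmat[r, j]
        Tmat[r, ] <- Tmat[r, ] / pv
        b[r] <- b[r] / pv
        other <- setdiff(seq_len(m), r)
        fac <- Tmat[other, j]
        Tmat[other, ] <- Tmat[other, ] - outer(fac, Tmat[r, ])
        b[other] <- b[other] - fac * b[r]
        basis[r] <- j
      }
      # rows with no eligible pivot are redundant; the artificial stays basic
      # at zero and is excluded from entering in phase 2
    }
  }

  c2 <- c(cc, rep(0, ntot - n))
  allowed <- rep(TRUE, ntot)
  allowed[art_cols] <- FALSE
  ph2 <- simplex_core(Tmat, b, c2, basis, allowed = allowed, tol = tol)
  if (ph2$status == "unbounded") return(list(status = "unbounded", x = NULL))
  x <- rep(0, ntot)
  x[ph2$basis] <- pmax(ph2$b, 0)
  list(status = "optimal", x = x[seq_len(n)])
}

# Full-tableau simplex iterations.  On entry the basic columns of Tmat must
# form an identity (true for the slack/artificial start and preserved between
# phases).  `allowed` masks columns that may enter (artificials in phase 2).
simplex_core <- function(Tmat, b, cvec, basis, allowed, tol = 1e-9,
                         max_iter = 50000L, stall_switch = 500L) {
  m <- nrow(Tmat)
  red <- cvec - drop(crossprod(Tmat, cvec[basis]))
  red[basis] <- 0
  obj <- sum(cvec[basis] * b)
  bland <- FALSE
  stall <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      warning("simplex iteration limit reached; returning current basis")
      return(list(status = "iteration_limit", Tmat = Tmat, b = b,
                  basis = basis, value = obj))
    }
    cand <- which(allowed & red < -tol)
    if (!length(cand)) {
      return(list(status = "optimal", Tmat = Tmat, b = b, basis = basis,
                  value = obj))
    }
    enter <- if (bland) cand[1L] else cand[which.min(red[cand])]
    col <- Tmat[, enter]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", Tmat = Tmat, b = b, basis = basis,
                  value = obj))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + 1e-12]
    leave <- ties[which.min(basis[ties])]
    pv <- col[leave]
    Tmat[leave, ] <- Tmat[leave, ] / pv
    b[leave] <- b[leave] / pv
    other <- setdiff(seq_len(m), leave)
    fac <- Tmat[other, enter]
    nz <- which(fac != 0)
    if (length(nz)) {
      rows <- other[nz]
      Tmat[rows, ] <- Tmat[rows, ] - outer(fac[nz], Tmat[leave, ])
      b[rows] <- b[rows] - fac[nz] * b[leave]
    }
    red <- red - red[enter] * Tmat[leave, ]
    red[enter] <- 0
    basis[leave] <- enter
    b[b < 0 & b > -1e-11] <- 0
    new_obj <- sum(cvec[basis] * b)
    if (new_obj < obj - 1e-12) stall <- 0L else {
      stall <- stall + 1L
      if (!bland && stall >= stall_switch) bland <- TRUE
    }
    obj <- new_obj
  }
}
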
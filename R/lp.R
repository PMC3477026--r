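## Dense bounded-variable simplex. This is the LP engine behind every fit,
## FVA pass and baseline in the package. Problems here are small (tens to a
## few hundred variables), so a two-phase full-inverse simplex in plain R is
## both fast enough and easy to keep numerically honest.

#' Solve a linear program with bounded variables
#'
#' Minimises (or maximises) `obj %*% x` subject to `Aeq %*% x == beq`,
#' `Aineq %*% x <= bineq`, and `lb <= x <= ub`. Lower bounds must be finite;
#' upper bounds may be `Inf`. Inequalities are converted internally to
#' equalities with slack variables. A two-phase bounded-variable simplex with
#' Bland anti-cycling is used; the pivot sequence is deterministic, so
#' repeated calls on one platform return bit-identical solutions.
#'
#' @param obj numeric objective coefficients, length n.
#' @param Aeq,beq equality constraints (matrix m x n, vector m); may be NULL.
#' @param Aineq,bineq `<=` inequality constraints; may be NULL.
#' @param lb,ub variable bounds, length n; `lb` finite, `ub` may be `Inf`.
#' @param maximize if TRUE, maximise the objective.
#' @param tol feasibility/optimality tolerance.
#'
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution, length n) and `objective` (its objective value).
#' @export
solveLP <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                    lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("solveLP requires finite lower bounds")
  if (any(lb > ub + tol))
    stop("infeasible bounds: lb > ub")
  Aeq <- if (is.null(Aeq)) matrix(0, 0, n) else as.matrix(Aeq)
  beq <- if (is.null(beq)) numeric(0) else as.numeric(beq)
  Aineq <- if (is.null(Aineq)) matrix(0, 0, n) else as.matrix(Aineq)
  bineq <- if (is.null(bineq)) numeric(0) else as.numeric(bineq)
  stopifnot(ncol(Aeq) == n, nrow(Aeq) == length(beq),
            ncol(Aineq) == n, nrow(Aineq) == length(bineq))

  k <- nrow(Aineq)                      # slack variables for <= rows
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)),
             cbind(Aineq, diag(1, k)))
  b <- c(beq, bineq)
  cost <- c(if (maximize) -obj else obj, rep(0, k))
  l <- c(lb, rep(0, k))
  u <- c(ub, rep(Inf, k))

  res <- .simplex_bounded(cost, A, b, l, u, tol = tol)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    list(status = "optimal", x = x,
         objective = sum(obj * x))
  } else {
    list(status = res$status, x = rep(NA_real_, n), objective = NA_real_)
  }
}

## Core: min cost'x s.t. A x = b, l <= x <= u (l finite, u possibly Inf).
## Phase 1 minimises the sum of artificial variables; phase 2 the true cost
## with artificials pinned to zero.
.simplex_bounded <- function(cost, A, b, l, u, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # pure box problem: each variable goes to its cheaper bound
    x <- ifelse(cost >= 0, l, u)
    if (any(cost < -tol & !is.finite(u)))
      return(list(status = "unbounded"))
    return(list(status = "optimal", x = x, objective = sum(cost * x)))
  }
  if (is.null(max_iter)) max_iter <- 200L * (n + m) + 2000L

  # nonbasic start: everything at its lower bound; artificials absorb b
  at_upper <- rep(FALSE, n + m)
  resid <- as.numeric(b - A %*% l)
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, rep(Inf, m))
  basis <- n + seq_len(m)
  art <- basis

  run_phase <- function(cvec, basis, at_upper, allow_enter) {
    degen <- 0L
    for (iter in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      xN <- ifelse(at_upper, uf, lf)
      xN[basis] <- 0
      xB <- as.numeric(Binv %*% (b - Afull %*% xN))
      y <- as.numeric(crossprod(Binv, cvec[basis]))
      nb <- setdiff(which(allow_enter), basis)
      if (length(nb) == 0L) break
      d <- cvec[nb] - as.numeric(crossprod(Afull[, nb, drop = FALSE], y))
      viol <- ifelse(at_upper[nb], d, -d)   # improvement if > 0
      cand <- which(viol > tol)
      if (length(cand) == 0L) {
        x <- xN; x[basis] <- xB
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    x = x))
      }
      # Dantzig rule, Bland fallback once degeneracy persists
      e <- if (degen > 2L * m) nb[min(cand)] else nb[cand[which.max(viol[cand])]]
      w <- as.numeric(Binv %*% Afull[, e])
      dir <- if (at_upper[e]) -1 else 1     # x_e moves by dir * t, t >= 0
      # basic variables move by -dir * t * w
      step <- uf[e] - lf[e]                 # bound-to-bound flip
      leave <- 0L; leave_to_upper <- FALSE
      for (r in seq_len(m)) {
        mv <- -dir * w[r]
        if (mv < -tol) {                    # decreasing, hits lower bound
          t_r <- (xB[r] - lf[basis[r]]) / (-mv)
          if (t_r < step - tol) { step <- t_r; leave <- r; leave_to_upper <- FALSE }
        } else if (mv > tol) {              # increasing, hits upper bound
          if (is.finite(uf[basis[r]])) {
            t_r <- (uf[basis[r]] - xB[r]) / mv
            if (t_r < step - tol) { step <- t_r; leave <- r; leave_to_upper <- TRUE }
          }
        }
      }
      if (!is.finite(step)) return(list(status = "unbounded"))
      step <- max(step, 0)
      degen <- if (step <= tol) degen + 1L else 0L
      if (leave == 0L) {                    # bound flip, basis unchanged
        at_upper[e] <- !at_upper[e]
      } else {
        lv <- basis[leave]
        at_upper[lv] <- leave_to_upper
        basis[leave] <- e
        at_upper[e] <- FALSE                # basic; status flag unused
      }
    }
    list(status = "maxiter")
  }

  # phase 1
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, basis, at_upper, allow_enter = rep(TRUE, n + m))
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  if (sum(ph1$x[art]) > 1e-6) return(list(status = "infeasible"))
  basis <- ph1$basis; at_upper <- ph1$at_upper
  # pin artificials at zero and forbid them from re-entering
  uf[art] <- 0
  allow <- c(rep(TRUE, n), rep(FALSE, m))
  allow[intersect(basis, art)] <- TRUE     # basic artificials stay (at 0)

  c2 <- c(cost, rep(0, m))
  ph2 <- run_phase(c2, basis, at_upper, allow_enter = allow)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "infeasible"))
  x <- ph2$x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cost * x))
}

#' Solve a small mixed-integer LP by branch and bound
#'
#' Depth-first branch and bound over the variables named in `binary`
#' (restricted to \{0,1\}), with plain LP relaxations solved by [solveLP()].
#' Intended for the small consistency MILPs used by the iMAT baseline, where
#' a handful of reactions carry activity indicators.
#'
#' @inheritParams solveLP
#' @param binary integer indices of 0/1 variables.
#' @return list with `status`, `x`, `objective` as in [solveLP()].
#' @export
solveMILP <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                      lb, ub, binary = integer(0), maximize = FALSE,
                      tol = 1e-6) {
  best <- list(objective = if (maximize) -Inf else Inf, x = NULL)
  lb0 <- lb; ub0 <- ub
  lb0[binary] <- pmax(lb0[binary], 0)
  ub0[binary] <- pmin(ub0[binary], 1)

  recurse <- function(lb, ub) {
    rel <- solveLP(obj, Aeq, beq, Aineq, bineq, lb, ub, maximize = maximize)
    if (rel$status != "optimal") return(invisible(NULL))
    if (maximize && rel$objective <= best$objective + tol) return(invisible(NULL))
    if (!maximize && rel$objective >= best$objective - tol) return(invisible(NULL))
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (length(binary) == 0L || max(frac) < tol) {
      best$objective <<- rel$objective
      best$x <<- rel$x
      if (length(binary)) best$x[binary] <<- round(best$x[binary])
      return(invisible(NULL))
    }
    j <- binary[which.max(frac)]
    # explore the rounded-up branch first (greedy on activation)
    for (val in if (rel$x[j] >= 0.5) c(1, 0) else c(0, 1)) {
      lb2 <- lb; ub2 <- ub
      lb2[j] <- val; ub2[j] <- val
      recurse(lb2, ub2)
    }
    invisible(NULL)
  }
  recurse(lb0, ub0)
  if (is.null(best$x)) return(list(status = "infeasible", x = NULL,
                                   objective = NA_real_))
  list(status = "optimal", x = best$x, objective = best$objective)
}
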
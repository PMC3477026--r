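## The core algorithm. A flux distribution is chosen to minimise
##   Z = sum_i (1/sigma_i) |v_i - s_i d_i|
## over steady-state flux vectors (N v = 0, L <= v <= U), where the sum runs
## over currently-irreversible reactions i with expression data, d_i is the
## expression-derived target magnitude, s_i in {+1,-1} the known flux
## direction, and 1/sigma_i the confidence weight. The absolute deviation is
## linearised with split variables (v_i = s_i d_i + d_i^+ - d_i^-,
## d^+, d^- >= 0). Reversible-reaction directions are assigned iteratively:
## after each fit, flux variability analysis under Z <= Z* detects reactions
## that can no longer change sign; these join the irreversible (and, with
## data, the scored) set and the fit repeats until the set stops growing.

## Build the LP pieces for the weighted fit in the variable space
## [v (n), d+ (k), d- (k)].
.build_fit_lp <- function(S, lb, ub, scored, sgn, d, sigma) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S); k <- length(scored)
  Aeq <- cbind(S, matrix(0, m, 2 * k))
  beq <- rep(0, m)
  if (k > 0) {
    dev <- matrix(0, k, n + 2 * k)
    dev[cbind(seq_len(k), scored)] <- 1
    dev[cbind(seq_len(k), n + seq_len(k))] <- -1
    dev[cbind(seq_len(k), n + k + seq_len(k))] <- 1
    Aeq <- rbind(Aeq, dev)
    beq <- c(beq, sgn * d[scored])
  }
  w <- if (k > 0) 1 / sigma[scored] else numeric(0)
  list(Aeq = Aeq, beq = beq,
       lb = c(lb, rep(0, 2 * k)), ub = c(ub, rep(Inf, 2 * k)),
       obj = c(rep(0, n), w, w), n = n, k = k)
}

#' Minimise the confidence-weighted flux deviation
#'
#' Solves the LP minimising `Z = sum_{i in scored} (1/sigma_i) |v_i - s_i
#' d_i|` over steady-state flux vectors of `model`. With an empty scored set
#' the optimum is Z* = 0 and the zero flux vector is returned when feasible.
#'
#' @param model a [MetabolicModel-class].
#' @param weights a [ReactionWeights-class] for the model.
#' @param scored integer indices (into the model's reactions) entering the
#'   objective; defaults to the initially irreversible reactions that carry
#'   expression data.
#' @param directions integer vector of signs (+1/-1), parallel to `scored`;
#'   defaults from the bound structure (`L >= 0` forward, `U <= 0` backward).
#' @return list with `objective` (Z*), `flux` (named vector) and `status`.
#' @export
solveWeightedFit <- function(model, weights, scored = NULL, directions = NULL) {
  n <- length(model@reactionIds)
  if (is.null(scored)) {
    irrev <- model@lowerBounds >= 0 | model@upperBounds <= 0
    scored <- which(irrev & weights@hasData)
  }
  if (is.null(directions))
    directions <- ifelse(model@lowerBounds[scored] >= 0, 1L, -1L)
  stopifnot(length(directions) == length(scored))

  if (length(scored) == 0L) {
    if (all(model@lowerBounds <= 0 & model@upperBounds >= 0)) {
      v <- stats::setNames(rep(0, n), model@reactionIds)
      return(list(objective = 0, flux = v, status = "optimal"))
    }
    lp <- .build_fit_lp(model@stoichiometry, model@lowerBounds,
                        model@upperBounds, integer(0), integer(0),
                        weights@d, weights@sigma)
    sol <- solveLP(lp$obj, Aeq = lp$Aeq, beq = lp$beq, lb = lp$lb, ub = lp$ub)
    if (sol$status != "optimal")
      stop("no steady-state flux distribution within bounds (", sol$status, ")")
    return(list(objective = 0,
                flux = stats::setNames(sol$x[seq_len(n)], model@reactionIds),
                status = sol$status))
  }

  lp <- .build_fit_lp(model@stoichiometry, model@lowerBounds,
                      model@upperBounds, scored, directions,
                      weights@d, weights@sigma)
  sol <- solveLP(lp$obj, Aeq = lp$Aeq, beq = lp$beq, lb = lp$lb, ub = lp$ub)
  if (sol$status != "optimal")
    stop("weighted fit LP did not solve: ", sol$status)
  list(objective = sol$objective,
       flux = stats::setNames(sol$x[seq_len(n)], model@reactionIds),
       status = sol$status)
}

#' Flux variability analysis under an objective ceiling
#'
#' For each requested reaction, minimises and maximises its flux over the
#' steady-state polytope intersected with `Z <= zstar + tol`, where Z is the
#' weighted deviation of [solveWeightedFit()] for the same scored set.
#' Reactions whose minimum is `>= -tol` can only run forward; those whose
#' maximum is `<= tol` only backward.
#'
#' @inheritParams solveWeightedFit
#' @param zstar optimal Z from [solveWeightedFit()] on the same problem.
#' @param tol absolute slack on the objective ceiling and on direction
#'   classification.
#' @param reactions integer indices to analyse; default all.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
fvaUnderObjective <- function(model, weights, scored, directions, zstar,
                              tol = 1e-9, reactions = NULL) {
  n <- length(model@reactionIds)
  if (is.null(reactions)) reactions <- seq_len(n)
  lp <- .build_fit_lp(model@stoichiometry, model@lowerBounds,
                      model@upperBounds, scored, directions,
                      weights@d, weights@sigma)
  Aineq <- matrix(lp$obj, 1)
  bineq <- zstar + tol
  vmin <- vmax <- rep(NA_real_, length(reactions))
  for (q in seq_along(reactions)) {
    j <- reactions[q]
    cc <- rep(0, length(lp$obj)); cc[j] <- 1
    lo <- solveLP(cc, Aeq = lp$Aeq, beq = lp$beq, Aineq = Aineq,
                  bineq = bineq, lb = lp$lb, ub = lp$ub)
    hi <- solveLP(cc, Aeq = lp$Aeq, beq = lp$beq, Aineq = Aineq,
                  bineq = bineq, lb = lp$lb, ub = lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA failed for reaction ", model@reactionIds[j],
           " (", lo$status, "/", hi$status, ")")
    vmin[q] <- lo$objective; vmax[q] <- hi$objective
  }
  data.frame(reaction_id = model@reactionIds[reactions],
             min = vmin, max = vmax, stringsAsFactors = FALSE)
}

#' Fit fluxes to expression with iterative direction assignment
#'
#' Runs the full estimation cycle: (1) minimise the weighted deviation Z over
#' the currently irreversible, expression-bearing reactions; (2) FVA under
#' `Z <= Z*` to find reversible reactions that have become unidirectional;
#' (3) clamp their bounds to the detected direction, add the data-bearing
#' ones to the scored set (target `+d` forward, `-d` backward), and repeat.
#' The irreversible set can only grow, so the loop terminates. Optionally the
#' final solution is replaced by the geometric centre of the alternate-optima
#' polytope ([centerSolution()]), making the result unique and reproducible.
#'
#' @inheritParams solveWeightedFit
#' @param tol absolute tolerance for the FVA objective ceiling and direction
#'   classification (flux units).
#' @param maxIter iteration cap (termination is guaranteed by monotonicity;
#'   the cap only guards against numerical pathology).
#' @param center logical; centre the final solution geometrically.
#' @return a [FitResult-class].
#' @export
iterativeFit <- function(model, weights, tol = 1e-9, maxIter = 100L,
                         center = TRUE) {
  n <- length(model@reactionIds)
  lb <- model@lowerBounds; ub <- model@upperBounds
  dir <- ifelse(lb >= 0, 1L, ifelse(ub <= 0, -1L, 0L))
  trace <- integer(0)
  sol <- NULL; scored <- integer(0); sgn <- integer(0)

  for (iter in seq_len(maxIter)) {
    work <- makeModel(model@metaboliteIds, model@reactionIds,
                      model@stoichiometry, lb, ub, gpr = model@gpr,
                      biomassId = model@biomassId,
                      exchangeIds = model@exchangeIds)
    scored <- which(dir != 0L & weights@hasData)
    sgn <- dir[scored]
    sol <- solveWeightedFit(work, weights, scored, sgn)
    trace <- c(trace, sum(dir != 0L))

    rev_idx <- which(dir == 0L)
    if (!length(rev_idx)) break
    fva <- fvaUnderObjective(work, weights, scored, sgn, sol$objective,
                             tol = tol, reactions = rev_idx)
    fwd <- fva$min >= -tol
    bwd <- !fwd & fva$max <= tol
    if (!any(fwd | bwd)) break
    for (q in seq_along(rev_idx)) {
      j <- rev_idx[q]
      if (fwd[q]) { dir[j] <- 1L; lb[j] <- max(lb[j], 0) }
      else if (bwd[q]) { dir[j] <- -1L; ub[j] <- min(ub[j], 0) }
    }
    if (iter == maxIter)
      stop("direction assignment did not settle within ", maxIter,
           " iterations; trace: ", paste(trace, collapse = " -> "))
  }

  flux <- sol$flux
  if (center) {
    work <- makeModel(model@metaboliteIds, model@reactionIds,
                      model@stoichiometry, lb, ub, gpr = model@gpr,
                      biomassId = model@biomassId,
                      exchangeIds = model@exchangeIds)
    flux <- centerSolution(work, weights, scored, sgn, sol$objective)
  }
  new("FitResult", flux = flux, objective = sol$objective,
      iterations = length(trace), irreversibleTrace = trace,
      scoredCount = length(scored),
      directions = stats::setNames(dir, model@reactionIds))
}

## Geometric centring of a polytope given in the fit variable space.
## Aeq/beq/Aineq/bineq describe the polytope over (v, auxiliaries); idx_v
## are the flux coordinates to centre. Each round: tight FVA bounds -> box
## midpoint p -> minimise the L1 distance to p -> restrict to that distance's
## optimal set and repeat, until the box collapses (max width < tol) or the
## width stops shrinking.
.center_polytope <- function(Aeq, beq, Aineq, bineq, lb, ub, idx_v,
                             tol = 1e-6, maxOuter = 50L) {
  nv <- length(idx_v)
  cur <- list(Aeq = Aeq, beq = beq, Aineq = Aineq, bineq = bineq,
              lb = lb, ub = ub)
  vsol <- NULL
  prev_width <- Inf
  for (outer in seq_len(maxOuter)) {
    a <- b <- rep(NA_real_, nv)
    for (q in seq_len(nv)) {
      cc <- rep(0, length(cur$lb)); cc[idx_v[q]] <- 1
      lo <- solveLP(cc, cur$Aeq, cur$beq, cur$Aineq, cur$bineq, cur$lb, cur$ub)
      hi <- solveLP(cc, cur$Aeq, cur$beq, cur$Aineq, cur$bineq, cur$lb, cur$ub,
                    maximize = TRUE)
      if (lo$status != "optimal" || hi$status != "optimal")
        stop("geometric centring: FVA subproblem failed (", lo$status, ")")
      a[q] <- lo$objective; b[q] <- hi$objective
    }
    width <- max(b - a)
    p <- (a + b) / 2
    if (width < tol) {
      if (is.null(vsol)) vsol <- p
      vsol[] <- p   # converged box: midpoint is the centre
      return(list(v = vsol, converged = TRUE, iterations = outer))
    }
    # min sum t, t >= |v - p|, in an extended space (append t variables)
    nold <- length(cur$lb)
    Tt <- diag(1, nv)
    Vv <- matrix(0, nv, nold); Vv[cbind(seq_len(nv), idx_v)] <- 1
    Aineq2 <- rbind(
      cbind(cur$Aineq, matrix(0, nrow(cur$Aineq), nv)),
      cbind(Vv, -Tt),        #  v - t <= p
      cbind(-Vv, -Tt))       # -v - t <= -p
    bineq2 <- c(cur$bineq, p, -p)
    Aeq2 <- cbind(cur$Aeq, matrix(0, nrow(cur$Aeq), nv))
    lb2 <- c(cur$lb, rep(0, nv)); ub2 <- c(cur$ub, (b - a) / 2 + tol)
    # flux coordinates also restricted to their attainable box
    lb2[idx_v] <- pmax(lb2[idx_v], a); ub2[idx_v] <- pmin(ub2[idx_v], b)
    obj <- c(rep(0, nold), rep(1, nv))
    sol <- solveLP(obj, Aeq2, cur$beq, Aineq2, bineq2, lb2, ub2)
    if (sol$status != "optimal")
      stop("geometric centring: L1 projection failed (", sol$status, ")")
    vsol <- sol$x[idx_v]
    if (prev_width - width < tol && outer > 1L) {
      warning("geometric centring stalled at box width ", format(width),
              "; returning last iterate")
      return(list(v = vsol, converged = FALSE, iterations = outer))
    }
    prev_width <- width
    # restrict to the L1-optimal set and iterate
    cur <- list(
      Aeq = Aeq2, beq = cur$beq,
      Aineq = rbind(Aineq2, matrix(obj, 1)),
      bineq = c(bineq2, sol$objective + tol * 1e-3),
      lb = lb2, ub = ub2)
  }
  warning("geometric centring did not converge in ", maxOuter,
          " iterations; returning last iterate")
  list(v = vsol, converged = FALSE, iterations = maxOuter)
}

#' Geometric centre of the alternate-optima polytope
#'
#' Among all flux vectors attaining the optimal weighted deviation
#' (`Z <= zstar + tol` together with steady state and bounds), selects the
#' central one by iterated variability-bounding: compute each reaction's
#' attainable flux interval, take the box midpoint, minimise the L1 distance
#' to it, restrict to the minimisers, and repeat until the attainable box
#' collapses. The result is unique and identical across repeated runs.
#'
#' @inheritParams fvaUnderObjective
#' @param convTol box-width convergence tolerance (flux units).
#' @param maxOuter outer iteration cap; on hitting it the last iterate is
#'   returned with a warning.
#' @return named flux vector.
#' @export
centerSolution <- function(model, weights, scored, directions, zstar,
                           tol = 1e-9, convTol = 1e-6, maxOuter = 50L) {
  n <- length(model@reactionIds)
  lp <- .build_fit_lp(model@stoichiometry, model@lowerBounds,
                      model@upperBounds, scored, directions,
                      weights@d, weights@sigma)
  Aineq <- matrix(lp$obj, 1); bineq <- zstar + tol
  res <- .center_polytope(lp$Aeq, lp$beq, Aineq, bineq, lp$lb, lp$ub,
                          idx_v = seq_len(n), tol = convTol,
                          maxOuter = maxOuter)
  stats::setNames(res$v, model@reactionIds)
}

#' Rescale fluxes to a measured glucose uptake
#'
#' The fit is carried out in expression units; physical units (mmol/h/gDW)
#' enter by rescaling the whole flux vector so that the glucose exchange flux
#' magnitude equals the measured uptake. All fluxes are multiplied by the
#' same positive factor, so flux ratios are unchanged.
#'
#' @param v named flux vector.
#' @param model a [MetabolicModel-class].
#' @param glucoseId id of the glucose exchange reaction.
#' @param measuredUptake measured glucose uptake (mmol/h/gDW, positive).
#' @return rescaled named flux vector.
#' @export
scaleToGlucose <- function(v, model, glucoseId, measuredUptake) {
  stopifnot(measuredUptake > 0)
  if (!glucoseId %in% model@reactionIds)
    stop("glucose exchange reaction not in model: ", glucoseId)
  g <- abs(v[[glucoseId]])
  if (g < 1e-12)
    stop("predicted glucose uptake is zero; cannot normalise")
  v * (measuredUptake / g)
}

#' Maximal steady-state residual of a flux vector
#'
#' Convenience check: `max |N v|` for a model and flux vector.
#'
#' @param model a [MetabolicModel-class].
#' @param v flux vector.
#' @return non-negative scalar.
#' @export
steadyStateResidual <- function(model, v) {
  max(abs(as.numeric(model@stoichiometry %*% v)))
}
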
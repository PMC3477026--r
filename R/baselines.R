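## Reference predictors the expression fit is compared against:
## biomass-maximising FBA (with geometric centring), fitted FBA (closest
## point to the measured exchanges on the biomass-optimal face), GIMME
## (penalises flux through below-threshold reactions subject to a biomass
## fraction) and iMAT (MILP maximising agreement between flux activity and
## high/low expression categories). All consume the same ReactionWeights as
## the main method, so the comparison isolates the algorithm.

#' Baseline configuration
#'
#' @param gimmeThreshold expression threshold below which flux is penalised;
#'   `NULL` (default) uses the 25th percentile of the data-bearing weights.
#' @param gimmeFraction required fraction of the maximal biomass rate, in
#'   `[0, 1]`.
#' @param imatLow,imatHigh quantile cut points (in `[0, 1]`, low < high)
#'   classifying data-bearing reactions into low/high expression; defaults
#'   are the tertiles.
#' @param imatEps minimum flux magnitude counting as "active" (flux units).
#' @return a list of class `BaselineConfig`.
#' @export
baselineConfig <- function(gimmeThreshold = NULL, gimmeFraction = 0.9,
                           imatLow = 1 / 3, imatHigh = 2 / 3, imatEps = 1) {
  stopifnot(gimmeFraction >= 0, gimmeFraction <= 1,
            imatLow < imatHigh, imatEps > 0)
  structure(list(gimmeThreshold = gimmeThreshold,
                 gimmeFraction = gimmeFraction,
                 imatLow = imatLow, imatHigh = imatHigh, imatEps = imatEps),
            class = "BaselineConfig")
}

## apply a glucose-uptake bound (uptake = negative exchange flux)
.bound_glucose <- function(model, glucoseId, glucoseUptake) {
  if (is.null(glucoseId)) return(model)
  j <- match(glucoseId, model@reactionIds)
  if (is.na(j)) stop("glucose exchange reaction not in model: ", glucoseId)
  lb <- model@lowerBounds; lb[j] <- -abs(glucoseUptake)
  makeModel(model@metaboliteIds, model@reactionIds, model@stoichiometry,
            lb, model@upperBounds, gpr = model@gpr,
            biomassId = model@biomassId, exchangeIds = model@exchangeIds)
}

.biomass_index <- function(model) {
  if (is.na(model@biomassId))
    stop("model has no biomass reaction; cannot run a biomass-based method")
  match(model@biomassId, model@reactionIds)
}

## maximise biomass; returns list(mu, lp) where lp is the steady-state LP
.max_biomass <- function(model) {
  n <- length(model@reactionIds)
  jb <- .biomass_index(model)
  cc <- rep(0, n); cc[jb] <- 1
  sol <- solveLP(cc, Aeq = as.matrix(model@stoichiometry), beq = rep(0, nrow(model@stoichiometry)),
                 lb = model@lowerBounds, ub = model@upperBounds,
                 maximize = TRUE)
  if (sol$status == "unbounded")
    stop("biomass objective is unbounded; bound the glucose uptake")
  if (sol$status != "optimal")
    stop("biomass FBA did not solve: ", sol$status)
  list(mu = sol$objective, jb = jb)
}

#' Biomass-maximising flux balance analysis
#'
#' Maximises the biomass reaction rate with glucose uptake bounded to the
#' measured value, then returns the geometric centre of the set of
#' alternate optima (all flux vectors attaining the maximal biomass rate).
#'
#' @param model a [MetabolicModel-class] with a biomass reaction.
#' @param glucoseId glucose exchange reaction id (uptake is constrained to at
#'   most `glucoseUptake` in magnitude); `NULL` to use model bounds as-is.
#' @param glucoseUptake measured glucose uptake, mmol/h/gDW.
#' @param center logical; centre the optimal face geometrically.
#' @return named flux vector.
#' @export
standardFBA <- function(model, glucoseId = NULL, glucoseUptake = NULL,
                        center = TRUE) {
  model <- .bound_glucose(model, glucoseId, glucoseUptake)
  n <- length(model@reactionIds)
  fb <- .max_biomass(model)
  if (!center) {
    cc <- rep(0, n); cc[fb$jb] <- 1
    sol <- solveLP(cc, Aeq = as.matrix(model@stoichiometry),
                   beq = rep(0, nrow(model@stoichiometry)),
                   lb = model@lowerBounds, ub = model@upperBounds,
                   maximize = TRUE)
    return(stats::setNames(sol$x, model@reactionIds))
  }
  # centre over {N v = 0, bounds, v_biomass >= mu*}
  Aineq <- matrix(0, 1, n); Aineq[1, fb$jb] <- -1
  bineq <- -fb$mu + 1e-9 * max(1, abs(fb$mu))
  res <- .center_polytope(as.matrix(model@stoichiometry),
                          rep(0, nrow(model@stoichiometry)),
                          Aineq, bineq, model@lowerBounds, model@upperBounds,
                          idx_v = seq_len(n))
  stats::setNames(res$v, model@reactionIds)
}

#' FBA fitted to measured exchange fluxes
#'
#' Two-stage LP: first maximise biomass, then — restricted to the
#' biomass-optimal face — minimise the summed absolute deviation between
#' predicted and measured exchange fluxes. With no measurements this reduces
#' to the centred biomass-FBA solution.
#'
#' @inheritParams standardFBA
#' @param measured named numeric vector: exchange reaction id -> measured
#'   flux (excretion positive, in the model's flux convention).
#' @return named flux vector.
#' @export
fittedFBA <- function(model, measured, glucoseId = NULL, glucoseUptake = NULL) {
  if (length(measured) == 0L)
    return(standardFBA(model, glucoseId, glucoseUptake))
  model <- .bound_glucose(model, glucoseId, glucoseUptake)
  n <- length(model@reactionIds)
  fb <- .max_biomass(model)
  ids <- names(measured)
  jm <- match(ids, model@reactionIds)
  if (anyNA(jm)) stop("measured exchange not in model: ",
                      paste(ids[is.na(jm)], collapse = ", "))
  k <- length(jm)
  # variables [v, t]; t_i >= |v_i - m_i|
  S <- as.matrix(model@stoichiometry)
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  beq <- rep(0, nrow(S))
  Vv <- matrix(0, k, n); Vv[cbind(seq_len(k), jm)] <- 1
  Tt <- diag(1, k)
  Abio <- matrix(0, 1, n + k); Abio[1, fb$jb] <- -1
  Aineq <- rbind(Abio,
                 cbind(Vv, -Tt),
                 cbind(-Vv, -Tt))
  bineq <- c(-fb$mu + 1e-9 * max(1, abs(fb$mu)), measured, -measured)
  sol <- solveLP(c(rep(0, n), rep(1, k)), Aeq, beq, Aineq, bineq,
                 lb = c(model@lowerBounds, rep(0, k)),
                 ub = c(model@upperBounds, rep(Inf, k)))
  if (sol$status != "optimal")
    stop("fitted FBA stage-2 LP did not solve: ", sol$status)
  stats::setNames(sol$x[seq_len(n)], model@reactionIds)
}

#' GIMME-style expression-consistent FBA
#'
#' Minimises summed flux through reactions whose expression weight falls
#' below a threshold, weighted by the shortfall, while requiring at least a
#' given fraction of the maximal biomass rate:
#' `min sum_i max(0, threshold - d_i) |v_i|` subject to steady state, bounds
#' and `v_biomass >= fraction * mu*`.
#'
#' @inheritParams standardFBA
#' @param weights a [ReactionWeights-class].
#' @param config a [baselineConfig()].
#' @return named flux vector.
#' @export
gimme <- function(model, weights, config = baselineConfig(),
                  glucoseId = NULL, glucoseUptake = NULL) {
  model <- .bound_glucose(model, glucoseId, glucoseUptake)
  n <- length(model@reactionIds)
  fb <- .max_biomass(model)
  thr <- config$gimmeThreshold
  if (is.null(thr))
    thr <- stats::quantile(weights@d[weights@hasData], 0.25, names = FALSE)
  pen <- ifelse(weights@hasData, pmax(0, thr - weights@d), 0)
  pen[is.na(pen)] <- 0
  ip <- which(pen > 0)
  k <- length(ip)
  S <- as.matrix(model@stoichiometry)
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  beq <- rep(0, nrow(S))
  Abio <- matrix(0, 1, n + k); Abio[1, fb$jb] <- -1
  bbio <- -config$gimmeFraction * fb$mu - 1e-9 * max(1, abs(fb$mu))
  if (k > 0) {
    Vv <- matrix(0, k, n); Vv[cbind(seq_len(k), ip)] <- 1
    Tt <- diag(1, k)
    Aineq <- rbind(Abio, cbind(Vv, -Tt), cbind(-Vv, -Tt))
    bineq <- c(bbio, rep(0, 2 * k))
  } else {
    Aineq <- Abio; bineq <- bbio
  }
  sol <- solveLP(c(rep(0, n), pen[ip]), Aeq, beq, Aineq, bineq,
                 lb = c(model@lowerBounds, rep(0, k)),
                 ub = c(model@upperBounds, rep(Inf, k)))
  if (sol$status != "optimal")
    stop("GIMME LP infeasible at biomass fraction ", config$gimmeFraction,
         "; try a lower fraction")
  stats::setNames(sol$x[seq_len(n)], model@reactionIds)
}

#' iMAT-style category-consistent flux prediction
#'
#' Classifies data-bearing reactions into high and low expression by weight
#' quantiles, then solves a MILP maximising the number of high-expression
#' reactions carrying flux of magnitude at least `imatEps` plus the number of
#' low-expression reactions carrying zero flux.
#'
#' @inheritParams gimme
#' @return named flux vector with attribute `"score"` (the attained
#'   consistency count).
#' @export
imat <- function(model, weights, config = baselineConfig(),
                 glucoseId = NULL, glucoseUptake = NULL) {
  model <- .bound_glucose(model, glucoseId, glucoseUptake)
  n <- length(model@reactionIds)
  dd <- weights@d[weights@hasData]
  if (!length(dd)) {
    sol <- solveWeightedFit(model, weights, scored = integer(0),
                            directions = integer(0))
    out <- sol$flux; attr(out, "score") <- 0
    return(out)
  }
  qlo <- stats::quantile(dd, config$imatLow, names = FALSE)
  qhi <- stats::quantile(dd, config$imatHigh, names = FALSE)
  high <- which(weights@hasData & weights@d >= qhi)
  low <- which(weights@hasData & weights@d <= qlo)
  eps <- config$imatEps
  L <- model@lowerBounds; U <- model@upperBounds
  S <- as.matrix(model@stoichiometry)

  nh <- length(high); nl <- length(low)
  nvar <- n + 2 * nh + nl       # [v, yfwd, ybwd, yzero]
  Aeq <- cbind(S, matrix(0, nrow(S), 2 * nh + nl))
  beq <- rep(0, nrow(S))
  rows <- list(); rhs <- numeric(0)
  add <- function(r, b) { rows[[length(rows) + 1L]] <<- r; rhs <<- c(rhs, b) }
  for (q in seq_len(nh)) {
    i <- high[q]
    r <- rep(0, nvar); r[i] <- -1; r[n + q] <- -(L[i] - eps)   # v >= L + y(eps - L)
    add(r, -L[i])
    r <- rep(0, nvar); r[i] <- 1; r[n + nh + q] <- U[i] + eps  # v <= U - y(U + eps)
    add(r, U[i])
    r <- rep(0, nvar); r[n + q] <- 1; r[n + nh + q] <- 1       # fwd + bwd <= 1
    add(r, 1)
  }
  for (q in seq_len(nl)) {
    i <- low[q]
    r <- rep(0, nvar); r[i] <- 1; r[n + 2 * nh + q] <- U[i]
    add(r, U[i])                                               # v <= U(1-y)
    r <- rep(0, nvar); r[i] <- -1; r[n + 2 * nh + q] <- -L[i]
    add(r, -L[i])                                              # v >= L(1-y)
  }
  Aineq <- if (length(rows)) do.call(rbind, rows) else NULL
  bineq <- if (length(rows)) rhs else NULL
  obj <- c(rep(0, n), rep(1, 2 * nh + nl))
  sol <- solveMILP(obj, Aeq, beq, Aineq, bineq,
                   lb = c(L, rep(0, 2 * nh + nl)),
                   ub = c(U, rep(1, 2 * nh + nl)),
                   binary = n + seq_len(2 * nh + nl), maximize = TRUE)
  if (sol$status != "optimal")
    stop("iMAT MILP did not solve: ", sol$status)
  out <- stats::setNames(sol$x[seq_len(n)], model@reactionIds)
  attr(out, "score") <- round(sol$objective)
  out
}

#' Recompute the iMAT consistency score of a flux vector
#'
#' Counts high-expression reactions with `|v| >= imatEps - tol` and
#' low-expression reactions with `|v| <= tol`, using the same quantile
#' categorisation as [imat()].
#'
#' @inheritParams imat
#' @param v named flux vector.
#' @param tol numeric tolerance.
#' @return integer score.
#' @export
imatScore <- function(model, weights, v, config = baselineConfig(),
                      tol = 1e-6) {
  dd <- weights@d[weights@hasData]
  qlo <- stats::quantile(dd, config$imatLow, names = FALSE)
  qhi <- stats::quantile(dd, config$imatHigh, names = FALSE)
  high <- which(weights@hasData & weights@d >= qhi)
  low <- which(weights@hasData & weights@d <= qlo)
  sum(abs(v[high]) >= config$imatEps - tol) + sum(abs(v[low]) <= tol)
}
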
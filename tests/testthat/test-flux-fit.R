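test_that("weighted fit reproduces hand-solvable chain optima", {
  m <- chain_model()
  w <- chain_weights(m)                       # d = (2,2), sigma = (1,1)
  sol <- solveWeightedFit(m, w)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_equal(unname(sol$flux[c("R1", "R2")]), c(2, 2), tolerance = 1e-8)
  expect_equal(sol$objective, chain_grid_oracle(c(2, 2), c(1, 1)),
               tolerance = 0.05)

  # capping the first reaction forces v = (1,1); both scored reactions then
  # deviate by 1, so Z* = 2 (the grid oracle agrees)
  m2 <- chain_model(ub_r1 = 1)
  sol2 <- solveWeightedFit(m2, chain_weights(m2))
  expect_equal(sol2$objective, chain_grid_oracle(c(2, 2), c(1, 1), ub_r1 = 1),
               tolerance = 0.05)
  expect_equal(unname(sol2$flux[c("R1", "R2")]), c(1, 1), tolerance = 1e-8)
})

test_that("LP optimum matches grid search across random chain problems", {
  set.seed(17)
  for (i in 1:12) {
    d <- round(runif(2, 0.5, 3.5), 1)
    sigma <- round(runif(2, 0.2, 2), 1)
    cap <- sample(c(1, 2, 1000), 1)
    m <- chain_model(ub_r1 = cap)
    w <- chain_weights(m, d = d, sigma = sigma)
    sol <- solveWeightedFit(m, w)
    want <- chain_grid_oracle(d, sigma, ub_r1 = cap)
    expect_lte(sol$objective, want + 1e-9)          # LP at least as good
    expect_gte(sol$objective, want - max(1 / sigma) * 0.11)  # grid resolution
  }
})

test_that("empty scored set yields Z* = 0 and the zero vector when feasible", {
  m <- chain_model()
  w <- mapExpression(m, newExpressionProfile(character(0), numeric(0)))
  sol <- solveWeightedFit(m, w)
  expect_equal(sol$objective, 0)
  expect_equal(unname(sol$flux), rep(0, 4))
})

test_that("FVA under the objective ceiling classifies directions", {
  m <- rev_chain_model()
  w <- rev_chain_weights(m)
  scored <- which(m@lowerBounds >= 0 & w@hasData)   # only Rd initially
  sol <- solveWeightedFit(m, w, scored, rep(1L, length(scored)))
  fva <- fvaUnderObjective(m, w, scored, rep(1L, length(scored)),
                           sol$objective, reactions = 2:4)
  expect_true(all(fva$min > 1e-9))   # Ra, Rb, Rc all forced forward
  # forcing one of them backward must raise Z: clamp Rb <= -0.5 (and let the
  # scored demand Rd run negative so the chain stays feasible) and re-solve
  lb <- m@lowerBounds; ub <- m@upperBounds
  ub[3] <- -0.5                      # Rb forced backward
  lb[c(5, 6)] <- -1000; ub[1] <- 1000  # let the rest of the chain follow
  m_neg <- makeModel(m@metaboliteIds, m@reactionIds, m@stoichiometry, lb, ub,
                     gpr = m@gpr)
  sol_neg <- solveWeightedFit(m_neg, w, scored, rep(1L, length(scored)))
  expect_gt(sol_neg$objective, sol$objective + 1e-6)

  # an already-irreversible forward reaction trivially has min >= 0
  fva_rd <- fvaUnderObjective(m, w, scored, rep(1L, length(scored)),
                              sol$objective, reactions = 5L)
  expect_gte(fva_rd$min, -1e-9)
})

test_that("a decoupled reversible cycle stays reversible", {
  m <- loop_model()
  w <- mapExpression(m, newExpressionProfile("g1", 2, 1))
  scored <- which((m@lowerBounds >= 0 | m@upperBounds <= 0) & w@hasData)
  sol <- solveWeightedFit(m, w, scored, rep(1L, length(scored)))
  fva <- fvaUnderObjective(m, w, scored, rep(1L, length(scored)),
                           sol$objective,
                           reactions = match(c("Lfwd", "Lbwd"),
                                             reactionIds(m)))
  expect_true(all(fva$min < -1e-6))
  expect_true(all(fva$max > 1e-6))
})

test_that("iterative fit terminates with a monotone irreversible trace", {
  # all initially irreversible: one solve, no growth
  m <- chain_model()
  fit <- iterativeFit(m, chain_weights(m))
  expect_equal(fit@iterations, 1L)
  expect_length(irreversibleTrace(fit), 1L)

  # three reversible reactions forced forward by the scored demand
  m2 <- rev_chain_model()
  fit2 <- iterativeFit(m2, rev_chain_weights(m2))
  tr <- irreversibleTrace(fit2)
  expect_true(all(diff(tr) >= 0))
  expect_gt(tr[length(tr)], tr[1])
  expect_equal(unname(reactionDirections(fit2)[c("Ra", "Rb", "Rc")]),
               c(1L, 1L, 1L))
  expect_equal(unname(fluxes(fit2)[c("Ra", "Rb", "Rc", "Rd")]),
               rep(2, 4), tolerance = 1e-6)

  # a reaction written against its forced flow is classified backward and
  # scored with a negated target
  m3 <- rev_chain_model(flip_third = TRUE)
  fit3 <- iterativeFit(m3, rev_chain_weights(m3))
  expect_equal(unname(reactionDirections(fit3)[["Rc"]]), -1L)
  expect_equal(unname(fluxes(fit3)[["Rc"]]), -2, tolerance = 1e-6)
  expect_equal(objectiveValue(fit3), 0, tolerance = 1e-6)
})

test_that("returned flux vectors satisfy steady state and optimality", {
  cases <- list(
    list(m = chain_model(), w = chain_weights(chain_model())),
    list(m = rev_chain_model(), w = rev_chain_weights(rev_chain_model())),
    list(m = rev_chain_model(TRUE), w = rev_chain_weights(rev_chain_model(TRUE))))
  for (case in cases) {
    m <- case$m; w <- case$w
    fit <- iterativeFit(m, w)
    expect_lte(steadyStateResidual(m, fluxes(fit)), 1e-6)
    expect_true(all(fluxes(fit) >= m@lowerBounds - 1e-6))
    expect_true(all(fluxes(fit) <= m@upperBounds + 1e-6))
    # re-evaluating Z at the returned vector reproduces the optimum
    scored <- which(reactionDirections(fit) != 0L & w@hasData)
    sgn <- reactionDirections(fit)[scored]
    z <- sum(1 / w@sigma[scored] *
               abs(fluxes(fit)[scored] - sgn * w@d[scored]))
    expect_equal(z, objectiveValue(fit),
                 tolerance = 1e-6 * max(1, objectiveValue(fit)))
  }
})

test_that("geometric centring returns the midpoint of a box-shaped face", {
  # two independent parallel splits; every Z*-optimal point has
  # Ra + Rb = 4 with Ra in [0,3], and Rc + Rd = 2 with Rc in [0,2]
  mets <- c("A", "B", "P", "Q")
  rxns <- c("EX_a", "Ra", "Rb", "EX_b", "EX_p", "Rc", "Rd", "EX_q")
  S <- matrix(0, 4, 8, dimnames = list(mets, rxns))
  S["A", "EX_a"] <- -1
  S["A", "Ra"] <- -1; S["B", "Ra"] <- 1
  S["A", "Rb"] <- -1; S["B", "Rb"] <- 1
  S["B", "EX_b"] <- -1
  S["P", "EX_p"] <- -1
  S["P", "Rc"] <- -1; S["Q", "Rc"] <- 1
  S["P", "Rd"] <- -1; S["Q", "Rd"] <- 1
  S["Q", "EX_q"] <- -1
  m <- makeModel(mets, rxns, S,
                 lb = c(-4, 0, 0, 0, -2, 0, 0, 0),
                 ub = c(-4, 3, 1000, 1000, -2, 2, 1000, 1000))
  w <- mapExpression(m, newExpressionProfile(character(0), numeric(0)))
  v <- centerSolution(m, w, integer(0), integer(0), zstar = 0)
  expect_equal(unname(v[c("Ra", "Rb")]), c(1.5, 2.5), tolerance = 1e-6)
  expect_equal(unname(v[c("Rc", "Rd")]), c(1, 1), tolerance = 1e-6)
  # repeated runs are identical
  v2 <- centerSolution(m, w, integer(0), integer(0), zstar = 0)
  expect_identical(v, v2)
})

test_that("centred solutions carry no net flux around a free cycle", {
  m <- loop_model()
  w <- mapExpression(m, newExpressionProfile("g1", 2, 1))
  fit <- iterativeFit(m, w, center = TRUE)
  expect_equal(unname(fluxes(fit)[c("Lfwd", "Lbwd")]), c(0, 0),
               tolerance = 1e-6)
  # a single-point polytope maps to that point
  expect_equal(unname(fluxes(fit)[["R1"]]), 2, tolerance = 1e-6)
})

test_that("glucose rescaling is exact, idempotent and scale-free", {
  m <- chain_model()
  fit <- iterativeFit(m, chain_weights(m))
  v <- fluxes(fit)
  sc <- scaleToGlucose(v, m, "EX_in", measuredUptake = 4)
  expect_equal(abs(sc[["EX_in"]]), 4)
  expect_equal(unname(sc), unname(v * 2))
  # identity when prediction equals the measurement
  expect_equal(scaleToGlucose(sc, m, "EX_in", 4), sc)
  # linearity: any positive prescaling is absorbed
  set.seed(5)
  for (c0 in runif(3, 0.1, 10))
    expect_equal(scaleToGlucose(c0 * v, m, "EX_in", 4), sc, tolerance = 1e-9)
  # zero predicted uptake cannot be normalised
  expect_error(scaleToGlucose(v * 0, m, "EX_in", 4), "zero")
})

test_that("rescaling the weights rescales the fit but not the scaled report", {
  m <- chain_model()
  f1 <- iterativeFit(m, chain_weights(m, d = c(2, 2)))
  f2 <- iterativeFit(m, chain_weights(m, d = c(6, 6)))
  expect_equal(unname(fluxes(f2)), unname(fluxes(f1) * 3), tolerance = 1e-6)
  s1 <- scaleToGlucose(fluxes(f1), m, "EX_in", 10)
  s2 <- scaleToGlucose(fluxes(f2), m, "EX_in", 10)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("planted fluxes are recovered exactly without noise", {
  spec <- fixtureSpec(nMetabolites = 4, nReactions = 6,
                      fractionReversible = 0, gprComplexity = 1,
                      noiseSd = 0, seed = 3)
  m <- makeToyModel(spec)
  planted <- plantFluxesAndExpression(m, spec)
  fit <- iterativeFit(m, mapExpression(m, planted$profile))
  expect_equal(unname(fluxes(fit)), unname(planted$flux), tolerance = 1e-6)
})

test_that("recovery error grows with expression noise", {
  rmse_at <- function(noise, seed) {
    spec <- fixtureSpec(nMetabolites = 4, nReactions = 6,
                        fractionReversible = 0, gprComplexity = 1,
                        noiseSd = noise, seed = seed)
    m <- makeToyModel(spec)
    planted <- plantFluxesAndExpression(m, spec)
    fit <- iterativeFit(m, mapExpression(m, planted$profile), center = FALSE)
    sqrt(mean((fluxes(fit) - planted$flux)^2))
  }
  seeds <- 1:10
  med <- vapply(c(0, 0.1, 0.5), function(ns)
    stats::median(vapply(seeds, function(s) rmse_at(ns, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) >= -1e-9))
  expect_equal(med[1], 0, tolerance = 1e-8)
})
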
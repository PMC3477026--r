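# split model: fixed nutrient uptake, biomass capped so the optimal face
# leaves a free range for the byproduct exchange
split_model <- function(biomass_cap = 2) {
  mets <- c("A", "B", "C")
  rxns <- c("EX_a", "R1", "R2", "biomass", "EX_c")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "EX_a"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R2"] <- -1; S["C", "R2"] <- 1
  S["B", "biomass"] <- -1
  S["C", "EX_c"] <- -1
  makeModel(mets, rxns, S,
            lb = c(-4, 0, 0, 0, 0), ub = c(0, 1000, 1000, biomass_cap, 1000),
            biomassId = "biomass")
}

test_that("biomass FBA routes all carbon to CO2 on the central-carbon toy", {
  m <- central_carbon_model()
  v <- standardFBA(m, glucoseId = "EX_glc", glucoseUptake = 5)
  expect_equal(excretionFlux(m, v, "EX_co2"), 30, tolerance = 1e-6)
  for (ex in c("EX_eth", "EX_gly", "EX_ace", "EX_tre", "EX_lac"))
    expect_equal(excretionFlux(m, v, ex), 0, tolerance = 1e-6)
  expect_equal(v[["biomass"]], 13, tolerance = 1e-6)  # 26 ATP/glc / 10
})

test_that("FBA biomass equals the bottleneck bound on a linear route", {
  mets <- c("A", "B")
  rxns <- c("EX_a", "R1", "biomass")
  S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
  S["A", "EX_a"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "biomass"] <- -1
  m <- makeModel(mets, rxns, S, lb = c(-10, 0, 0), ub = c(0, 3, 1000),
                 biomassId = "biomass")
  v <- standardFBA(m)
  expect_equal(v[["biomass"]], 3, tolerance = 1e-9)
})

test_that("FBA errors without a biomass reaction; centring keeps its value", {
  m <- chain_model()   # no biomass
  expect_error(standardFBA(m), "biomass")
  m2 <- central_carbon_model()
  v_c <- standardFBA(m2, "EX_glc", 5, center = TRUE)
  v_u <- standardFBA(m2, "EX_glc", 5, center = FALSE)
  expect_equal(v_c[["biomass"]], v_u[["biomass"]], tolerance = 1e-6)
})

test_that("fitted FBA clamps free exchanges to measurements within the face", {
  m <- split_model(biomass_cap = 2)
  # optimal face: biomass = 2, EX_c free in [0, 2]
  v_in <- fittedFBA(m, measured = c(EX_c = 1))
  expect_equal(v_in[["EX_c"]], 1, tolerance = 1e-8)
  expect_equal(v_in[["biomass"]], 2, tolerance = 1e-8)
  v_out <- fittedFBA(m, measured = c(EX_c = 5))
  expect_equal(v_out[["EX_c"]], 2, tolerance = 1e-8)   # nearest face bound
  # biomass never sacrificed for the fit
  expect_equal(v_out[["biomass"]], standardFBA(m)[["biomass"]],
               tolerance = 1e-6)
  # empty measurements reduce to the centred biomass solution
  expect_equal(fittedFBA(m, measured = numeric(0)), standardFBA(m),
               tolerance = 1e-8)
})

test_that("GIMME silences a below-threshold detour", {
  mets <- c("A", "B")
  rxns <- c("EX_a", "R_hi", "R_lo", "biomass", "EX_b")
  S <- matrix(0, 2, 5, dimnames = list(mets, rxns))
  S["A", "EX_a"] <- -1
  S["A", "R_hi"] <- -1; S["B", "R_hi"] <- 1
  S["A", "R_lo"] <- -1; S["B", "R_lo"] <- 1
  S["B", "biomass"] <- -1
  S["B", "EX_b"] <- -1
  m <- makeModel(mets, rxns, S, lb = c(-4, 0, 0, 0, 0),
                 ub = c(0, 1000, 1000, 1000, 1000), biomassId = "biomass")
  pr <- newExpressionProfile(c("ghi", "glo"), c(10, 0.1), c(1, 1))
  m@gpr[c(2, 3)] <- list(parseGpr("ghi"), parseGpr("glo"))
  w <- mapExpression(m, pr)
  v <- gimme(m, w, baselineConfig(gimmeThreshold = 1, gimmeFraction = 0.9))
  expect_equal(v[["R_lo"]], 0, tolerance = 1e-8)
  expect_gte(v[["biomass"]], 0.9 * 4 - 1e-6)
  # threshold below every weight: objective is zero, biomass still honoured
  v2 <- gimme(m, w, baselineConfig(gimmeThreshold = 0.01,
                                   gimmeFraction = 0.9))
  expect_gte(v2[["biomass"]], 0.9 * 4 - 1e-6)
})

test_that("iMAT activates the high branch and silences the low branch", {
  mets <- c("A", "B")
  rxns <- c("EX_a", "R_hi", "R_lo", "EX_b")
  S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
  S["A", "EX_a"] <- -1
  S["A", "R_hi"] <- -1; S["B", "R_hi"] <- 1
  S["A", "R_lo"] <- -1; S["B", "R_lo"] <- 1
  S["B", "EX_b"] <- -1
  m <- makeModel(mets, rxns, S, lb = c(-10, 0, 0, 0),
                 ub = c(0, 1000, 1000, 1000))
  m@gpr[c(2, 3)] <- list(parseGpr("ghi"), parseGpr("glo"))
  w <- mapExpression(m, newExpressionProfile(c("ghi", "glo"), c(10, 0.1),
                                             c(1, 1)))
  cfg <- baselineConfig(imatEps = 1)
  v <- imat(m, w, cfg)
  expect_gte(abs(v[["R_hi"]]), 1 - 1e-6)
  expect_equal(v[["R_lo"]], 0, tolerance = 1e-8)
  # both indicators satisfiable simultaneously -> score 2, and the reported
  # score equals the score recomputed from the flux vector
  expect_equal(attr(v, "score"), 2)
  expect_equal(imatScore(m, w, v, cfg), 2)
})

test_that("baseline configuration is validated", {
  expect_error(baselineConfig(gimmeFraction = 1.5))
  expect_error(baselineConfig(imatLow = 0.8, imatHigh = 0.2))
  expect_error(baselineConfig(imatEps = 0))
})
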
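# Fixtures built in code. Flux convention throughout: every exchange
# consumes its metabolite, so positive exchange flux is excretion and
# uptakes run negative.

# linear chain A -> B -> C with uptake and excretion exchanges; the two
# internal reactions carry single-gene GPRs g1, g2
chain_model <- function(ub_r1 = 1000) {
  S <- matrix(0, 3, 4,
              dimnames = list(c("A", "B", "C"),
                              c("EX_in", "R1", "R2", "EX_out")))
  S["A", "EX_in"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  S["C", "EX_out"] <- -1
  makeModel(rownames(S), colnames(S), S,
            lb = c(-1000, 0, 0, 0), ub = c(0, ub_r1, 1000, 1000),
            gpr = list(NULL, parseGpr("g1"), parseGpr("g2"), NULL))
}

chain_weights <- function(model, d = c(2, 2), sigma = c(1, 1)) {
  mapExpression(model, newExpressionProfile(c("g1", "g2"), d, sigma))
}

# brute-force grid minimiser of the weighted deviation on the chain:
# v1 = v2 by mass balance; exchanges follow
chain_grid_oracle <- function(d, sigma, ub_r1 = 1000, grid = seq(0, 4, 0.1)) {
  best <- Inf
  for (v in grid[grid <= ub_r1]) {
    z <- sum(1 / sigma * abs(c(v, v) - d))
    if (z < best) best <- z
  }
  best
}

# diamond: A can reach B through R_top or R_rev (reversible), B is excreted;
# only R_top has expression data. Used for FVA direction-forcing tests.
diamond_model <- function() {
  S <- matrix(0, 2, 4,
              dimnames = list(c("A", "B"),
                              c("EX_in", "R_top", "R_rev", "EX_out")))
  S["A", "EX_in"] <- -1
  S["A", "R_top"] <- -1; S["B", "R_top"] <- 1
  S["A", "R_rev"] <- -1; S["B", "R_rev"] <- 1
  S["B", "EX_out"] <- -1
  makeModel(rownames(S), colnames(S), S,
            lb = c(-1000, 0, -1000, 0), ub = c(0, 1000, 1000, 1000),
            gpr = list(NULL, parseGpr("gtop"), NULL, NULL))
}

# two-reaction reversible loop decoupled from a scored chain
loop_model <- function() {
  S <- matrix(0, 4, 6,
              dimnames = list(c("A", "B", "X", "Y"),
                              c("EX_in", "R1", "EX_out", "Lfwd", "Lbwd",
                                "EX_x")))
  S["A", "EX_in"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "EX_out"] <- -1
  # loop: X <-> Y by two reversible reactions (a closed 2-cycle)
  S["X", "Lfwd"] <- -1; S["Y", "Lfwd"] <- 1
  S["Y", "Lbwd"] <- -1; S["X", "Lbwd"] <- 1
  S["X", "EX_x"] <- -1
  makeModel(rownames(S), colnames(S), S,
            lb = c(-1000, 0, 0, -5, -5, 0), ub = c(0, 1000, 1000, 5, 5, 0),
            gpr = list(NULL, parseGpr("g1"), NULL, NULL, NULL, NULL))
}

# reversible middle segment forced forward (or backward) by a scored
# downstream demand; used for FVA and direction-assignment tests
rev_chain_model <- function(flip_third = FALSE) {
  mets <- c("A", "B", "C", "D", "E")
  rxns <- c("EX_in", "Ra", "Rb", "Rc", "Rd", "EX_out")
  S <- matrix(0, 5, 6, dimnames = list(mets, rxns))
  S["A", "EX_in"] <- -1
  S["A", "Ra"] <- -1; S["B", "Ra"] <- 1
  S["B", "Rb"] <- -1; S["C", "Rb"] <- 1
  if (flip_third) { S["D", "Rc"] <- -1; S["C", "Rc"] <- 1 }   # written D -> C
  else            { S["C", "Rc"] <- -1; S["D", "Rc"] <- 1 }
  S["D", "Rd"] <- -1; S["E", "Rd"] <- 1
  S["E", "EX_out"] <- -1
  makeModel(mets, rxns, S,
            lb = c(-1000, -1000, -1000, -1000, 0, 0),
            ub = c(0, 1000, 1000, 1000, 1000, 1000),
            gpr = list(NULL, parseGpr("ga"), parseGpr("gb"),
                       parseGpr("gc"), parseGpr("gd"), NULL))
}

rev_chain_weights <- function(model, d = 2)
  mapExpression(model, newExpressionProfile(c("ga", "gb", "gc", "gd"),
                                            rep(d, 4), rep(1, 4)))

# recursive brute-force GPR evaluator, independent of evaluateGpr
brute_eval <- function(node, genes, means, sds) {
  if (is.null(node)) return(NULL)
  if (node$kind == "gene") {
    i <- match(node$gene, genes)
    if (is.na(i)) return(NULL)
    return(c(means[i], sds[i]))
  }
  vals <- lapply(node$children, brute_eval, genes = genes, means = means,
                 sds = sds)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (node$kind == "and") {
    if (length(vals) < length(node$children)) return(NULL)
    mm <- vapply(vals, `[`, numeric(1), 1)
    ss <- vapply(vals, `[`, numeric(1), 2)
    cand <- which(mm <= min(mm))
    pick <- cand[which.min(ss[cand])]
    return(c(mm[pick], ss[pick]))
  }
  if (!length(vals)) return(NULL)
  c(sum(vapply(vals, `[`, numeric(1), 1)),
    sqrt(sum(vapply(vals, `[`, numeric(1), 2)^2)))
}

# small central-carbon toy: glucose either fermented (-> ethanol + CO2,
# low ATP yield) or respired (-> CO2, high ATP yield); biomass drains ATP.
# Minor products (glycerol, acetate, trehalose, lactate) are reachable but
# cost glucose without yielding ATP.
central_carbon_model <- function() {
  mets <- c("GLC", "ETH", "CO2", "ATP", "GLY", "ACE", "TRE", "LAC")
  rxns <- c("EX_glc", "ferment", "respire", "biomass",
            "to_gly", "to_ace", "to_tre", "to_lac",
            "EX_eth", "EX_co2", "EX_gly", "EX_ace", "EX_tre", "EX_lac")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["GLC", "EX_glc"] <- -1
  S[c("GLC", "ETH", "CO2", "ATP"), "ferment"] <- c(-1, 2, 2, 2)
  S[c("GLC", "CO2", "ATP"), "respire"] <- c(-1, 6, 26)
  S["ATP", "biomass"] <- -10
  S[c("GLC", "GLY"), "to_gly"] <- c(-1, 2)
  S[c("GLC", "ACE"), "to_ace"] <- c(-1, 2)
  S[c("GLC", "TRE"), "to_tre"] <- c(-1, 1)
  S[c("GLC", "LAC"), "to_lac"] <- c(-1, 2)
  for (ex in c("EX_eth", "EX_co2", "EX_gly", "EX_ace", "EX_tre", "EX_lac"))
    S[sub("EX_", "", toupper(ex)), ex] <- -1
  lb <- c(-10, rep(0, length(rxns) - 1))
  ub <- rep(1000, length(rxns)); ub[1] <- 0
  makeModel(mets, rxns, S, lb, ub, biomassId = "biomass")
}

# the six measured exometabolome fluxes at 75% maximal biomass, mapped to
# the central-carbon toy exchanges
central_carbon_observations <- function() {
  tab <- exometabolomeTable("75")
  data.frame(metabolite = tab$metabolite,
             exchange_id = c("EX_eth", "EX_co2", "EX_gly", "EX_ace",
                             "EX_tre", "EX_lac"),
             flux = tab$experiment, stringsAsFactors = FALSE)
}
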
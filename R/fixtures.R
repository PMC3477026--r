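## Synthetic toy models with planted flux patterns and matching expression
## profiles. These emulate the study design — a stoichiometric network with
## GPR-annotated reactions plus absolute expression that reflects flux
## magnitudes — at a scale where every algorithm can be checked against
## brute force. Generation is a pure function of the seed.

#' Specification for a synthetic toy model
#'
#' @param nMetabolites number of internal metabolites (>= 2).
#' @param nReactions total reactions including the nutrient-uptake and
#'   product exchanges; must be at least `nMetabolites + 1` (a linear chain
#'   with two exchanges).
#' @param fractionReversible fraction of internal reactions made reversible.
#' @param gprComplexity maximal GPR tree depth (1 = single-gene rules).
#' @param noiseSd sd of the truncated-normal noise added to planted
#'   expression means (expression units).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @param withBiomass include a biomass pseudo-reaction draining the terminal
#'   metabolite.
#' @return a list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nMetabolites = 6, nReactions = 10,
                        fractionReversible = 0.3, gprComplexity = 2,
                        noiseSd = 0.1, seed = 1L, withBiomass = FALSE) {
  stopifnot(nMetabolites >= 2, nReactions >= nMetabolites + 1,
            fractionReversible >= 0, fractionReversible <= 1,
            gprComplexity >= 1, noiseSd >= 0)
  structure(list(nMetabolites = nMetabolites, nReactions = nReactions,
                 fractionReversible = fractionReversible,
                 gprComplexity = gprComplexity, noiseSd = noiseSd,
                 seed = as.integer(seed), withBiomass = withBiomass),
            class = "FixtureSpec")
}

## evaluate thunk with a private RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## random GPR tree of depth <= depth over a gene pool (possibly reusing
## genes, emulating promiscuous enzymes)
.random_gpr <- function(pool, depth) {
  if (depth <= 1 || stats::runif(1) < 0.5)
    return(list(kind = "gene", gene = sample(pool, 1)))
  kind <- sample(c("and", "or"), 1)
  nk <- sample(2:3, 1)
  kids <- lapply(seq_len(nk), function(i) .random_gpr(pool, depth - 1))
  .gpr_node(kind, kids)
}

#' Generate a connected synthetic metabolic model
#'
#' Builds a linear backbone `M1 -> M2 -> ... -> Mk` fed by a nutrient
#' exchange on `M1` and drained by a product exchange on `Mk`, then adds
#' random shortcut reactions between backbone metabolites until
#' `nReactions` is reached. A chosen fraction of internal reactions is made
#' reversible; internal reactions receive random GPR trees. All exchanges
#' consume their metabolite, so positive exchange flux is excretion and the
#' nutrient uptake runs negative.
#'
#' @param spec a [fixtureSpec()].
#' @return a [MetabolicModel-class].
#' @export
makeToyModel <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .with_seed(spec$seed, {
    m <- spec$nMetabolites
    mets <- sprintf("M%02d", seq_len(m))
    rxn <- list()  # each: list(id, stoich = named numeric, lb, ub, gpr)
    add <- function(id, stoich, lb, ub, gpr = NULL)
      rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr)
    add("EX_nutrient", stats::setNames(-1, mets[1]), -10, 0)
    n_internal_target <- spec$nReactions - 2L - spec$withBiomass
    genes <- sprintf("G%03d", seq_len(max(4L, n_internal_target + 2L)))
    # depth-1 rules get a gene of their own (one gene, one reaction), so the
    # planted expression maps back exactly; deeper trees draw from a shared
    # pool, which reintroduces promiscuous enzymes
    rxn_gpr <- function(ri) {
      if (spec$gprComplexity == 1L) list(kind = "gene", gene = genes[ri])
      else .random_gpr(genes, spec$gprComplexity)
    }
    ri <- 0L
    for (i in seq_len(m - 1L)) {
      ri <- ri + 1L
      add(sprintf("R%02d", ri),
          stats::setNames(c(-1, 1), mets[c(i, i + 1L)]), 0, 1000,
          gpr = rxn_gpr(ri))
    }
    while (ri < n_internal_target) {
      ri <- ri + 1L
      ij <- sort(sample(m, 2))
      add(sprintf("R%02d", ri),
          stats::setNames(c(-1, 1), mets[ij]), 0, 1000,
          gpr = rxn_gpr(ri))
    }
    internal <- which(vapply(rxn, function(r) startsWith(r$id, "R"), logical(1)))
    nrev <- round(spec$fractionReversible * length(internal))
    if (nrev > 0)
      for (j in sample(internal, nrev)) rxn[[j]]$lb <- -1000
    add("EX_product", stats::setNames(-1, mets[m]), 0, 1000)
    if (spec$withBiomass)
      add("biomass", stats::setNames(-1, mets[m]), 0, 1000)

    ids <- vapply(rxn, `[[`, character(1), "id")
    S <- matrix(0, m, length(rxn), dimnames = list(mets, ids))
    for (j in seq_along(rxn)) S[names(rxn[[j]]$stoich), j] <- rxn[[j]]$stoich
    makeModel(mets, ids, S,
              lb = vapply(rxn, `[[`, numeric(1), "lb"),
              ub = vapply(rxn, `[[`, numeric(1), "ub"),
              gpr = lapply(rxn, `[[`, "gpr"),
              biomassId = if (spec$withBiomass) "biomass" else NA_character_,
              exchangeIds = c("EX_nutrient", "EX_product"))
  })
}

#' Plant a feasible flux pattern and matching expression profile
#'
#' Samples a nonzero steady-state flux vector `v*` of the model (by
#' maximising nutrient uptake plus a small random tie-breaking objective over
#' the bounded flux polytope, capped at |v| <= 10), then builds an expression
#' profile in which each gene's mean is the largest planted flux magnitude
#' among the reactions it catalyses, plus truncated-normal noise, with
#' sd = `noiseSd`. With zero noise, single-gene reactions map back exactly to
#' their planted flux magnitudes.
#'
#' @param model a [MetabolicModel-class] from [makeToyModel()].
#' @param spec the [fixtureSpec()] used to build it (supplies noise and
#'   seed; the planting seed is offset so model and plant draws differ).
#' @return list with `flux` (named planted vector `v*`) and `profile`
#'   (an [ExpressionProfile-class]).
#' @export
plantFluxesAndExpression <- function(model, spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  n <- length(model@reactionIds)
  .with_seed(spec$seed + 1000L, {
    S <- as.matrix(model@stoichiometry)
    lb <- pmax(model@lowerBounds, -10)
    ub <- pmin(model@upperBounds, 10)
    vstar <- NULL
    jup <- match("EX_nutrient", model@reactionIds)
    for (attempt in seq_len(100L)) {
      cc <- stats::rnorm(n, 0, 0.05)
      if (!is.na(jup)) cc[jup] <- cc[jup] + 1     # drive uptake negative
      sol <- solveLP(cc, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub)
      if (sol$status == "optimal" && max(abs(sol$x)) > 1e-6) {
        vstar <- sol$x
        break
      }
    }
    if (is.null(vstar))
      stop("could not sample a nonzero feasible flux pattern")
    names(vstar) <- model@reactionIds

    gene_rxn <- list()
    for (j in seq_len(n))
      for (g in gprGenes(model@gpr[[j]]))
        gene_rxn[[g]] <- c(gene_rxn[[g]], j)
    genes <- names(gene_rxn)
    means <- vapply(genes, function(g) {
      base <- max(abs(vstar[gene_rxn[[g]]]))
      max(0, base + stats::rnorm(1, 0, spec$noiseSd))
    }, numeric(1))
    list(flux = vstar,
         profile = newExpressionProfile(genes, means,
                                        sd = rep(spec$noiseSd, length(genes))))
  })
}

#' Emit a complete synthetic data set to a directory
#'
#' Writes the toy model as SBML, the expression profile as TSV and the
#' planted fluxes as TSV — a self-contained input set for the command-line
#' interface.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated `model`, `flux`, `profile`
#'   and file paths.
#' @export
simulateDataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- makeToyModel(spec)
  planted <- plantFluxesAndExpression(model, spec)
  paths <- list(model = file.path(dir, "model.xml"),
                expression = file.path(dir, "expression.tsv"),
                flux = file.path(dir, "planted_flux.tsv"))
  writeSBMLModel(model, paths$model)
  utils::write.table(expressionTable(planted$profile), paths$expression,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(reaction_id = names(planted$flux), flux = planted$flux),
    paths$flux, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(list(model = model), planted, list(paths = paths)))
}
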
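test_that("toy model survives an SBML write/read round trip", {
  spec <- fixtureSpec(seed = 11)
  m1 <- makeToyModel(spec)
  tf <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(m1, tf)
  m2 <- readSBMLModel(tf)
  expect_equal(metaboliteIds(m2), metaboliteIds(m1))
  expect_equal(reactionIds(m2), reactionIds(m1))
  expect_equal(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m1)))
  expect_equal(unname(lowerBounds(m2)), m1@lowerBounds)
  expect_equal(unname(upperBounds(m2)), m1@upperBounds)
  expect_equal(lapply(gprRules(m2), gprToString),
               lapply(gprRules(m1), gprToString))
  expect_setequal(exchangeIds(m2), exchangeIds(m1))
})

test_that("level-3 fbc models are read: bounds, gene labels, associations", {
  m <- readSBMLModel(system.file("extdata", "example_fbc.xml",
                                 package = "fluxcor"))
  expect_equal(reactionIds(m), c("EX_A", "R_AB", "EX_B"))
  expect_equal(unname(lowerBounds(m)), c(-1000, 0, 0))
  expect_equal(unname(upperBounds(m)), c(1000, 1000, 1000))
  expect_equal(gprToString(gprRules(m)[["R_AB"]]),
               "(YJR109C and YOR303W) or YJL130C")
  expect_setequal(exchangeIds(m), c("EX_A", "EX_B"))
})

test_that("reversibility flags derive from the bound structure", {
  m <- readSBMLModel(system.file("extdata", "example_fbc.xml",
                                 package = "fluxcor"))
  expect_equal(unname(reversibleFlags(m)),
               unname(lowerBounds(m) < 0 & upperBounds(m) > 0))
})

test_that("exchange reaction columns have exactly one nonzero entry", {
  for (seed in c(2, 5, 9)) {
    m <- makeToyModel(fixtureSpec(seed = seed))
    S <- as.matrix(stoichiometry(m))
    nz <- colSums(S[, match(exchangeIds(m), reactionIds(m)),
                    drop = FALSE] != 0)
    expect_true(all(nz == 1))
  }
})

test_that("missing bounds default by reversibility with a warning", {
  # minimal SBML without any bound parameters
  txt <- '<?xml version="1.0"?>
  <sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies><species id="A" compartment="c" boundaryCondition="false"/></listOfSpecies>
  <listOfReactions>
    <reaction id="fwd" reversible="false">
      <listOfReactants><speciesReference species="A"/></listOfReactants>
    </reaction>
    <reaction id="rev" reversible="true">
      <listOfProducts><speciesReference species="A"/></listOfProducts>
    </reaction>
  </listOfReactions></model></sbml>'
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, tf)
  expect_warning(m <- readSBMLModel(tf), "defaulting")
  expect_equal(unname(lowerBounds(m)), c(0, -1000))
  expect_equal(unname(upperBounds(m)), c(1000, 1000))
})

test_that("an SBML model with no reactions loads as an empty model", {
  txt <- '<?xml version="1.0"?>
  <sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="empty"><listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies><species id="A" compartment="c"/></listOfSpecies>
  <listOfReactions/></model></sbml>'
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, tf)
  m <- readSBMLModel(tf)
  expect_length(reactionIds(m), 0)
  expect_equal(metaboliteIds(m), "A")
})

test_that("unreadable path raises an error", {
  expect_error(readSBMLModel(file.path(tempdir(), "nope_missing.xml")),
               "cannot read")
})

test_that("an independent SBML implementation agrees on a written model", {
  # cobrapy (Python) re-reads a toy model written by this package and
  # reports the same dimensions, bounds and GPR gene sets
  m <- makeToyModel(fixtureSpec(seed = 4))
  tf <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(m, tf)
  script <- paste(
    "import cobra, json, sys, warnings",
    "warnings.filterwarnings('ignore')",
    "mod = cobra.io.read_sbml_model(sys.argv[1])",
    "out = {'n_rxn': len(mod.reactions), 'n_met': len(mod.metabolites),",
    "  'bounds': {r.id: [r.lower_bound, r.upper_bound] for r in mod.reactions},",
    "  'genes': {r.id: sorted(g.id for g in r.genes) for r in mod.reactions}}",
    "print(json.dumps(out))", sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- suppressWarnings(
    tryCatch(system2("python", c(sf, tf), stdout = TRUE, stderr = FALSE),
             error = function(e) character(0)))
  ok <- length(res) > 0 && nzchar(res[length(res)]) &&
    startsWith(trimws(res[length(res)]), "{")
  expect_true(ok)
  got <- jsonlite::fromJSON(res[length(res)])
  expect_equal(got$n_rxn, length(reactionIds(m)))
  expect_equal(got$n_met, length(metaboliteIds(m)))
  for (r in reactionIds(m)) {
    expect_equal(got$bounds[[r]],
                 c(lowerBounds(m)[[r]], upperBounds(m)[[r]]))
    gg <- if (is.null(got$genes[[r]])) character(0) else got$genes[[r]]
    expect_setequal(gg, gprGenes(gprRules(m)[[r]]))
  }
})

test_that("reactionTable dumps id, bounds, reversibility and GPR strings", {
  m <- chain_model()
  tab <- reactionTable(m)
  expect_equal(tab$reaction_id, reactionIds(m))
  expect_equal(tab$gpr, c("", "g1", "g2", ""))
  expect_equal(tab$reversible, unname(reversibleFlags(m)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  reactionTable(m, tf)
  back <- read.delim(tf, stringsAsFactors = FALSE)
  back$gpr[is.na(back$gpr)] <- ""
  expect_equal(back$reaction_id, tab$reaction_id)
  expect_equal(back$lower, tab$lower)
})
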
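Package: fluxcor
Title: Expression-Constrained Flux Prediction for Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts steady-state metabolic flux distributions by integrating
    absolute gene-expression measurements (e.g. RPKM from RNA-Seq) with a
    genome-scale metabolic model. Gene expression is mapped onto reactions
    through Boolean gene-protein-reaction rules (AND = enzyme complex, bounded
    by its least-expressed component; OR = isoenzymes, summed), and a flux
    distribution is found by minimising the confidence-weighted absolute
    deviation between fluxes and the expression-derived reaction weights under
    stoichiometric steady-state and bound constraints. Directions of reversible
    reactions are fixed iteratively by flux variability analysis, a unique
    representative solution is selected by geometric centring of the
    alternate-optima polytope, and predictions are compared with measured
    exometabolome fluxes via the coefficient of determination. Baseline
    predictors (biomass-maximising FBA, fitted FBA, GIMME, iMAT) are included
    for comparison, together with a synthetic-model generator for testing.
    Includes a self-contained dense bounded-variable simplex solver and SBML
    reader/writer (Level 2 notes and Level 3 fbc gene associations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
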
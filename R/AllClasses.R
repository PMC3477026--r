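#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums t
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' Holds the stoichiometric matrix N (metabolites x reactions), per-reaction
#' flux bounds, parsed gene-protein-reaction (GPR) Boolean trees, and the
#' identities of exchange and biomass pseudo-reactions. Steady-state flux
#' vectors v satisfy N v = 0 with L_i <= v_i <= U_i. A reaction is reversible
#' iff its bounds straddle zero (L_i < 0 < U_i).
#'
#' @slot metaboliteIds character, one id per row of the stoichiometric matrix.
#' @slot reactionIds character, one id per column.
#' @slot stoichiometry sparse `Matrix` of stoichiometric coefficients.
#' @slot lowerBounds,upperBounds numeric flux bounds per reaction.
#' @slot gpr list parallel to `reactionIds`; each element a GPR tree (see
#'   [parseGpr()]) or `NULL` when the reaction has no gene association.
#' @slot biomassId id of the biomass pseudo-reaction, or `NA_character_`.
#' @slot exchangeIds ids of exchange reactions (single nonzero stoichiometric
#'   entry; they carry uptake/excretion flux across the system boundary).
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    metaboliteIds = "character",
    reactionIds   = "character",
    stoichiometry = "Matrix",
    lowerBounds   = "numeric",
    upperBounds   = "numeric",
    gpr           = "list",
    biomassId     = "character",
    exchangeIds   = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  S <- object@stoichiometry
  if (nrow(S) != length(object@metaboliteIds))
    msgs <- c(msgs, "rows of stoichiometry must match metaboliteIds")
  if (ncol(S) != length(object@reactionIds))
    msgs <- c(msgs, "columns of stoichiometry must match reactionIds")
  nr <- length(object@reactionIds)
  if (length(object@lowerBounds) != nr || length(object@upperBounds) != nr)
    msgs <- c(msgs, "bounds must have one entry per reaction")
  if (any(object@lowerBounds > object@upperBounds))
    msgs <- c(msgs, "lower bound exceeds upper bound for some reaction")
  if (length(object@gpr) != nr)
    msgs <- c(msgs, "gpr list must have one entry per reaction")
  if (anyDuplicated(object@reactionIds))
    msgs <- c(msgs, "duplicate reaction ids")
  if (anyDuplicated(object@metaboliteIds))
    msgs <- c(msgs, "duplicate metabolite ids")
  if (!all(object@exchangeIds %in% object@reactionIds))
    msgs <- c(msgs, "exchangeIds must be reaction ids")
  if (length(object@exchangeIds)) {
    nz <- Matrix::colSums(S[, match(object@exchangeIds, object@reactionIds),
                            drop = FALSE] != 0)
    if (any(nz != 1))
      msgs <- c(msgs, "exchange reactions must have exactly one nonzero coefficient")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReactionWeights: expression-derived reaction targets
#'
#' Per-reaction target flux magnitude d_i (in expression units, e.g. RPKM)
#' and its uncertainty sigma_i, obtained by evaluating each reaction's GPR
#' tree against an expression profile. `hasData` is FALSE for reactions with
#' no GPR or whose required genes are all unmeasured; such reactions never
#' enter the weighted-deviation objective.
#'
#' @slot reactionIds character.
#' @slot d numeric targets (NA where `hasData` is FALSE).
#' @slot sigma numeric uncertainties, strictly positive where `hasData`.
#' @slot hasData logical.
#' @exportClass ReactionWeights
setClass("ReactionWeights",
  representation(
    reactionIds = "character",
    d           = "numeric",
    sigma       = "numeric",
    hasData     = "logical"
  )
)

setValidity("ReactionWeights", function(object) {
  n <- length(object@reactionIds)
  msgs <- character(0)
  if (length(object@d) != n || length(object@sigma) != n ||
      length(object@hasData) != n)
    msgs <- c(msgs, "all slots must have one entry per reaction")
  if (any(object@hasData & !(object@sigma > 0), na.rm = TRUE))
    msgs <- c(msgs, "sigma must be > 0 wherever hasData is TRUE")
  if (length(msgs)) msgs else TRUE
})

#' ExpressionProfile: absolute per-gene expression
#'
#' Gene-level means and standard deviations of absolute expression
#' (e.g. RPKM). Means and sds are non-negative; gene ids are unique.
#'
#' @slot genes character gene ids.
#' @slot mean,sd numeric, parallel to `genes`.
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  representation(genes = "character", mean = "numeric", sd = "numeric")
)

setValidity("ExpressionProfile", function(object) {
  msgs <- character(0)
  n <- length(object@genes)
  if (length(object@mean) != n || length(object@sd) != n)
    msgs <- c(msgs, "mean and sd must be parallel to genes")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "duplicate gene ids")
  if (any(object@mean < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative expression mean")
  if (any(object@sd < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative expression sd")
  if (length(msgs)) msgs else TRUE
})

#' FitResult: outcome of the iterative expression fit
#'
#' @slot flux named numeric flux vector (one entry per reaction).
#' @slot objective optimal weighted absolute deviation Z*.
#' @slot iterations number of solve/FVA cycles performed.
#' @slot irreversibleTrace size of the irreversible set at each iteration.
#' @slot scoredCount reactions entering the objective at termination.
#' @slot directions named integer: +1 forward, -1 backward, 0 still reversible.
#' @exportClass FitResult
setClass("FitResult",
  representation(
    flux              = "numeric",
    objective         = "numeric",
    iterations        = "integer",
    irreversibleTrace = "integer",
    scoredCount       = "integer",
    directions        = "integer"
  )
)

setValidity("FitResult", function(object) {
  msgs <- character(0)
  if (length(object@objective) != 1 || is.na(object@objective) ||
      object@objective < -1e-9)
    msgs <- c(msgs, "objective must be a single non-negative number")
  tr <- object@irreversibleTrace
  if (length(tr) > 1 && any(diff(tr) < 0))
    msgs <- c(msgs, "irreversible set size must never decrease")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: predicted vs measured exometabolome fluxes
#'
#' @slot table data.frame with one row per measured metabolite: observed flux
#'   and one column of glucose-normalised predictions per method.
#' @slot r2 named numeric, coefficient of determination per method.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(table = "data.frame", r2 = "numeric")
)

setValidity("EvaluationReport", function(object) {
  if (any(object@r2 > 1 + 1e-12, na.rm = TRUE))
    "R^2 cannot exceed 1" else TRUE
})
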
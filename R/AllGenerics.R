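## Accessor generics. Slot access from user code goes through these.

#' @rdname MetabolicModel-class
#' @param object,x a `MetabolicModel`.
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("reversibleFlags", function(object) standardGeneric("reversibleFlags"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("exchangeIds", function(object) standardGeneric("exchangeIds"))
#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassId", function(object) standardGeneric("biomassId"))

setMethod("reactionIds", "MetabolicModel", function(object) object@reactionIds)
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metaboliteIds)
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoichiometry)
setMethod("lowerBounds", "MetabolicModel",
          function(object) stats::setNames(object@lowerBounds, object@reactionIds))
setMethod("upperBounds", "MetabolicModel",
          function(object) stats::setNames(object@upperBounds, object@reactionIds))
setMethod("reversibleFlags", "MetabolicModel", function(object)
  stats::setNames(object@lowerBounds < 0 & object@upperBounds > 0,
                  object@reactionIds))
setMethod("gprRules", "MetabolicModel",
          function(object) stats::setNames(object@gpr, object@reactionIds))
setMethod("exchangeIds", "MetabolicModel", function(object) object@exchangeIds)
setMethod("biomassId", "MetabolicModel", function(object) object@biomassId)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", length(object@metaboliteIds), "metabolites x",
      length(object@reactionIds), "reactions\n")
  cat("  reversible:", sum(object@lowerBounds < 0 & object@upperBounds > 0),
      " exchange:", length(object@exchangeIds),
      " with GPR:", sum(!vapply(object@gpr, is.null, logical(1))), "\n")
  if (!is.na(object@biomassId))
    cat("  biomass reaction:", object@biomassId, "\n")
})

#' @rdname ReactionWeights-class
#' @param object a `ReactionWeights`.
#' @export
setGeneric("weightTable", function(object) standardGeneric("weightTable"))
setMethod("weightTable", "ReactionWeights", function(object)
  data.frame(reaction_id = object@reactionIds, d = object@d,
              sigma = object@sigma, has_data = object@hasData,
              stringsAsFactors = FALSE))

setMethod("show", "ReactionWeights", function(object) {
  cat("ReactionWeights:", length(object@reactionIds), "reactions,",
      sum(object@hasData), "with expression data\n")
})

#' @rdname FitResult-class
#' @param object a `FitResult`.
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
setMethod("fluxes", "FitResult", function(object) object@flux)

#' @rdname FitResult-class
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
setMethod("objectiveValue", "FitResult", function(object) object@objective)

#' @rdname FitResult-class
#' @export
setGeneric("irreversibleTrace", function(object) standardGeneric("irreversibleTrace"))
setMethod("irreversibleTrace", "FitResult", function(object) object@irreversibleTrace)

#' @rdname FitResult-class
#' @export
setGeneric("reactionDirections", function(object) standardGeneric("reactionDirections"))
setMethod("reactionDirections", "FitResult", function(object) object@directions)

setMethod("show", "FitResult", function(object) {
  cat("FitResult: Z* =", format(object@objective, digits = 6),
      "after", object@iterations, "iteration(s)\n")
  cat("  irreversible set sizes:",
      paste(object@irreversibleTrace, collapse = " -> "), "\n")
  cat("  reactions scored:", object@scoredCount, "\n")
})

#' @rdname ExpressionProfile-class
#' @param object an `ExpressionProfile`.
#' @export
setGeneric("expressionTable", function(object) standardGeneric("expressionTable"))
setMethod("expressionTable", "ExpressionProfile", function(object)
  data.frame(gene_id = object@genes, mean = object@mean, sd = object@sd,
             stringsAsFactors = FALSE))

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile:", length(object@genes), "genes\n")
})

#' @rdname EvaluationReport-class
#' @param object an `EvaluationReport`.
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
setMethod("reportTable", "EvaluationReport", function(object) object@table)

#' @rdname EvaluationReport-class
#' @export
setGeneric("rSquaredValues", function(object) standardGeneric("rSquaredValues"))
setMethod("rSquaredValues", "EvaluationReport", function(object) object@r2)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", nrow(object@table), "metabolites\n")
  print(object@table, digits = 4)
  cat("R^2 per method:\n")
  print(round(object@r2, 3))
})
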
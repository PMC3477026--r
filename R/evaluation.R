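## Predicted-vs-measured exometabolome comparison. Excreted fluxes are
## reported positive, uptakes negative. Predictions are read off the scaled
## flux vectors at user-specified exchange reactions and summarised per
## method with the coefficient of determination.

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the observed mean.
#' 1 means a perfect match; 0 is what predicting the observed mean for every
#' point achieves; negative values mean the prediction is worse than the
#' mean predictor. Not a squared correlation: no refitting is involved.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return scalar, at most 1.
#' @export
rSquared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0)
    stop("observed values are all identical; R^2 undefined (SS_tot = 0)")
  1 - sum((observed - predicted)^2) / sst
}

#' Excretion flux of an exchange reaction
#'
#' Converts a model-convention exchange flux into the reporting convention
#' (excretion positive, uptake negative) using the sign of the exchange
#' reaction's single stoichiometric coefficient: a positive flux through an
#' exchange that consumes its metabolite is an excretion.
#'
#' @param model a [MetabolicModel-class].
#' @param v named flux vector.
#' @param exchangeId exchange reaction id.
#' @return scalar excretion flux.
#' @export
excretionFlux <- function(model, v, exchangeId) {
  j <- match(exchangeId, model@reactionIds)
  if (is.na(j)) stop("exchange reaction not in model: ", exchangeId)
  coef <- model@stoichiometry[, j]
  s <- sign(sum(coef[coef != 0]))
  -s * v[[exchangeId]]
}

#' Build an evaluation report over measured exometabolome fluxes
#'
#' For each method's (already glucose-scaled) flux vector, extracts the
#' predicted excretion flux of every observed metabolite and computes the
#' per-method coefficient of determination against the measurements.
#'
#' @param model a [MetabolicModel-class].
#' @param observations data.frame with columns `metabolite`,
#'   `exchange_id` (the matching model exchange reaction) and `flux`
#'   (measured, excretion positive, mmol/h/gDW).
#' @param methodFluxes named list of flux vectors, one per method.
#' @return an [EvaluationReport-class].
#' @export
buildReport <- function(model, observations, methodFluxes) {
  stopifnot(is.data.frame(observations),
            all(c("metabolite", "exchange_id", "flux") %in% names(observations)),
            is.list(methodFluxes), length(methodFluxes) >= 1,
            !is.null(names(methodFluxes)))
  bad <- setdiff(observations$exchange_id, model@reactionIds)
  if (length(bad))
    stop("observed metabolite(s) unmatched in model: ",
         paste(observations$metabolite[observations$exchange_id %in% bad],
               collapse = ", "))
  if (anyDuplicated(observations$exchange_id))
    stop("each metabolite must map to exactly one exchange reaction")
  tab <- data.frame(metabolite = observations$metabolite,
                    observed = observations$flux,
                    stringsAsFactors = FALSE)
  r2 <- numeric(0)
  for (m in names(methodFluxes)) {
    pred <- vapply(observations$exchange_id, function(id)
      excretionFlux(model, methodFluxes[[m]], id), numeric(1))
    tab[[m]] <- unname(pred)
    r2[[m]] <- rSquared(tab$observed, tab[[m]])
  }
  new("EvaluationReport", table = tab, r2 = r2)
}

#' Bundled exometabolome flux tables
#'
#' Measured and per-method predicted exometabolome fluxes (mmol/h/gDW,
#' glucose-normalised, excretion positive) for Saccharomyces cerevisiae
#' permittistat cultures held at 75% or 85% of the maximal biomass level:
#' ethanol, CO2, glycerol, acetate, trehalose and lactate. Used by the
#' package's examples and reference checks.
#'
#' @param condition `"75"` or `"85"` (% of maximal biomass).
#' @return data.frame with a `metabolite` column, an `experiment` column and
#'   one column per prediction method.
#' @export
exometabolomeTable <- function(condition = c("75", "85")) {
  condition <- match.arg(condition)
  path <- system.file("extdata",
                      paste0("yeast_exometabolome_", condition, ".tsv"),
                      package = "fluxcor", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
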
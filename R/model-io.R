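## SBML reading/writing on top of xml2. Level 2 models carry GPRs in the
## notes field ("GENE_ASSOCIATION: ...") and bounds in kineticLaw parameters;
## Level 3 models use the fbc extension (flux-bound parameters and
## gene-product association trees). Both are normalised to one
## MetabolicModel representation. XPath uses local-name() so namespace
## prefixes never matter.

DEFAULT_BOUND <- 1000

#' Construct a MetabolicModel from parts
#'
#' Exchange reactions are auto-detected (stoichiometric column with exactly
#' one nonzero entry) when `exchangeIds` is NULL.
#'
#' @param metaboliteIds,reactionIds character identifier vectors.
#' @param S stoichiometric matrix (metabolites x reactions); coerced sparse.
#' @param lb,ub numeric flux bounds per reaction.
#' @param gpr list of GPR trees (or NULLs), one per reaction; defaults to all
#'   NULL.
#' @param biomassId biomass reaction id or `NA`.
#' @param exchangeIds exchange reaction ids, or NULL to auto-detect.
#' @return a validated [MetabolicModel-class] object.
#' @export
makeModel <- function(metaboliteIds, reactionIds, S, lb, ub,
                      gpr = NULL, biomassId = NA_character_,
                      exchangeIds = NULL) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(metaboliteIds, reactionIds)
  if (is.null(gpr)) gpr <- vector("list", length(reactionIds))
  if (is.null(exchangeIds)) {
    nz <- Matrix::colSums(S != 0)
    exchangeIds <- reactionIds[nz == 1]
  }
  new("MetabolicModel",
      metaboliteIds = as.character(metaboliteIds),
      reactionIds = as.character(reactionIds),
      stoichiometry = S,
      lowerBounds = as.numeric(lb), upperBounds = as.numeric(ub),
      gpr = gpr, biomassId = biomassId,
      exchangeIds = as.character(exchangeIds))
}

#' Read a genome-scale metabolic model from SBML
#'
#' Supports SBML Level 2 (bounds as `LOWER_BOUND`/`UPPER_BOUND` kineticLaw
#' parameters, GPRs as `GENE_ASSOCIATION:` lines in reaction notes) and
#' Level 3 with the fbc extension (flux-bound parameters,
#' `geneProductAssociation` trees resolved through `listOfGeneProducts`
#' labels). Species flagged `boundaryCondition="true"` are excluded from the
#' stoichiometric matrix, so boundary-crossing reactions appear as exchange
#' reactions. Reactions without explicit bounds default to
#' `[-1000, 1000]` when reversible and `[0, 1000]` otherwise, with a warning.
#'
#' @param path path to an SBML file.
#' @param biomassId optional biomass reaction id; if NULL, the first reaction
#'   whose id or name contains "biomass" (case-insensitive) is used.
#' @return a [MetabolicModel-class].
#' @export
readSBMLModel <- function(path, biomassId = NULL) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path)
  doc <- xml2::read_xml(path)

  sp_nodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- tolower(ifelse(is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")),
                                "false", xml2::xml_attr(sp_nodes, "boundaryCondition")))
  mets <- sp_id[sp_boundary != "true"]

  # fbc / L3 global flux-bound parameters
  par_nodes <- xml2::xml_find_all(doc,
    "./*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  # fbc gene products: id -> label
  gp_nodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"), xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  nr <- length(rxn_nodes)
  rxn_id <- xml2::xml_attr(rxn_nodes, "id")
  rxn_name <- xml2::xml_attr(rxn_nodes, "name")
  rev_attr <- xml2::xml_attr(rxn_nodes, "reversible")
  reversible <- ifelse(is.na(rev_attr), TRUE, tolower(rev_attr) == "true")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- rep(NA_real_, nr); ub <- rep(NA_real_, nr)
  gpr <- vector("list", nr)
  missing_bounds <- character(0)

  for (j in seq_len(nr)) {
    rn <- rxn_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      keep <- sp %in% mets
      if (any(keep)) {
        ii <- c(ii, match(sp[keep], mets)); jj <- c(jj, rep(j, sum(keep)))
        xx <- c(xx, st[keep])
      }
    }

    # bounds: fbc attributes first, then kineticLaw parameters
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(par_val)) lb[j] <- par_val[[lbref]]
    if (!is.na(ubref) && ubref %in% names(par_val)) ub[j] <- par_val[[ubref]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      kl <- xml2::xml_find_all(rn, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter']"))
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kid[is.na(kid)] <- xml2::xml_attr(kl, "name")[is.na(kid)]
        kv <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lb[j]) && "LOWER_BOUND" %in% kid)
          lb[j] <- kv[match("LOWER_BOUND", kid)]
        if (is.na(ub[j]) && "UPPER_BOUND" %in% kid)
          ub[j] <- kv[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lb[j]) || is.na(ub[j])) {
      missing_bounds <- c(missing_bounds, rxn_id[j])
      if (is.na(lb[j])) lb[j] <- if (reversible[j]) -DEFAULT_BOUND else 0
      if (is.na(ub[j])) ub[j] <- DEFAULT_BOUND
    }

    # GPR: legacy notes, then fbc association tree
    notes <- xml2::xml_find_first(rn, "./*[local-name()='notes']")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      mm <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
      if (length(mm)) {
        rule <- trimws(sub("^GENE_ASSOCIATION:", "", mm[[1]]))
        gpr[[j]] <- parseGpr(rule)
      }
    }
    if (is.null(gpr[[j]])) {
      assoc <- xml2::xml_find_first(rn,
        "./*[local-name()='geneProductAssociation']")
      if (!inherits(assoc, "xml_missing")) {
        kids <- xml2::xml_find_all(assoc, "./*")
        if (length(kids)) gpr[[j]] <- .fbc_to_gpr(kids[[1]], gp_label)
      }
    }
  }

  if (length(missing_bounds))
    warning("no explicit bounds for ", length(missing_bounds),
            " reaction(s); defaulting to +/-", DEFAULT_BOUND, ": ",
            paste(utils::head(missing_bounds, 5), collapse = ", "),
            if (length(missing_bounds) > 5) ", ..." else "")

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), nr))
  if (is.null(biomassId)) {
    hit <- grepl("biomass", rxn_id, ignore.case = TRUE) |
      (!is.na(rxn_name) & grepl("biomass", rxn_name, ignore.case = TRUE))
    biomassId <- if (any(hit)) rxn_id[which(hit)[1]] else NA_character_
  }
  makeModel(mets, rxn_id, S, lb, ub, gpr = gpr, biomassId = biomassId)
}

.fbc_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (!is.na(ref) && ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(list(kind = "gene", gene = gene))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_find_all(node, "./*"), .fbc_to_gpr,
                   gp_label = gp_label)
    return(.gpr_node(nm, kids))
  }
  stop("unsupported fbc association element: ", nm)
}

#' Write a MetabolicModel to SBML (Level 2)
#'
#' Emits SBML Level 2 Version 4 with bounds as `LOWER_BOUND`/`UPPER_BOUND`
#' kineticLaw parameters and GPRs as `GENE_ASSOCIATION:` note lines — the
#' same dialect [readSBMLModel()] reads, so write/read round-trips are exact.
#' Intended for the synthetic toy models used in testing.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSBMLModel <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  mdl <- xml2::xml_add_child(doc, "model", id = "fluxcor_model")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "c", size = "1")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model@metaboliteIds)
    xml2::xml_add_child(los, "species", id = m, compartment = "c",
                        initialConcentration = "0",
                        boundaryCondition = "false")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  S <- model@stoichiometry
  for (j in seq_along(model@reactionIds)) {
    rev <- model@lowerBounds[j] < 0 && model@upperBounds[j] > 0
    rn <- xml2::xml_add_child(lor, "reaction", id = model@reactionIds[j],
                              reversible = if (rev) "true" else "false")
    rule <- gprToString(model@gpr[[j]])
    if (nzchar(rule)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", rule))
    }
    col <- S[, j]
    nzi <- which(col != 0)
    reac <- nzi[col[nzi] < 0]; prod <- nzi[col[nzi] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lr, "speciesReference",
                            species = model@metaboliteIds[i],
                            stoichiometry = format(-col[i], digits = 15))
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lp, "speciesReference",
                            species = model@metaboliteIds[i],
                            stoichiometry = format(col[i], digits = 15))
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    xml2::xml_add_child(math, "ci", " FLUX_VALUE ")
    lop <- xml2::xml_add_child(kl, "listOfParameters")
    xml2::xml_add_child(lop, "parameter", id = "LOWER_BOUND",
                        value = format(model@lowerBounds[j], digits = 15))
    xml2::xml_add_child(lop, "parameter", id = "UPPER_BOUND",
                        value = format(model@upperBounds[j], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Tabulate a model's reactions
#'
#' @param model a [MetabolicModel-class].
#' @param path optional path; when given, the table is also written as TSV.
#' @return data.frame with id, bounds, reversibility and GPR string.
#' @export
reactionTable <- function(model, path = NULL) {
  df <- data.frame(
    reaction_id = model@reactionIds,
    lower = model@lowerBounds,
    upper = model@upperBounds,
    reversible = model@lowerBounds < 0 & model@upperBounds > 0,
    gpr = vapply(model@gpr, gprToString, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
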
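## Mapping absolute expression onto reactions through GPR logic:
## AND (complex) -> the least-expressed component bounds the complex, so the
## minimum mean is taken, together with that component's sd;
## OR (isoenzymes) -> capacities add, so means are summed and variances are
## added under the assumption that genes are uncorrelated.

#' Construct an ExpressionProfile
#'
#' @param genes character gene ids (unique).
#' @param mean,sd numeric non-negative expression means and standard
#'   deviations (e.g. RPKM), parallel to `genes`. `sd` defaults to zero.
#' @return an [ExpressionProfile-class].
#' @export
newExpressionProfile <- function(genes, mean, sd = rep(0, length(genes))) {
  new("ExpressionProfile", genes = as.character(genes),
      mean = as.numeric(mean), sd = as.numeric(sd))
}

#' Read an expression profile from a delimited table
#'
#' Expects columns `gene_id`, `mean` and optionally `sd` (tab- or
#' comma-separated, with header). Rows lacking an sd get sd = 0 and are
#' reported in a warning, since a zero sd will later be floored to keep
#' confidence weights finite.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return an [ExpressionProfile-class].
#' @export
readExpression <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs gene_id and mean columns")
  names(df)[1:2] <- c("gene_id", "mean")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene ids in expression table: ",
         paste(unique(dup), collapse = ", "))
  if (any(df$mean < 0))
    stop("negative expression mean for: ",
         paste(df$gene_id[df$mean < 0], collapse = ", "))
  if (ncol(df) >= 3) {
    names(df)[3] <- "sd"
    miss <- is.na(df$sd)
  } else {
    df$sd <- NA_real_
    miss <- rep(TRUE, nrow(df))
  }
  if (any(miss)) {
    df$sd[miss] <- 0
    warning(sum(miss), " gene(s) without sd; set to 0 (will be floored ",
            "during mapping)")
  }
  newExpressionProfile(df$gene_id, df$mean, df$sd)
}

#' Evaluate a GPR tree against an expression profile
#'
#' Returns the reaction-level expression estimate implied by the Boolean
#' rule: a gene leaf takes the gene's (mean, sd); an AND node (enzyme
#' complex) takes the child with the minimal mean — ties go to the child with
#' the smaller sd; an OR node (isoenzymes) sums the child means and adds
#' their variances. Genes absent from the profile are treated as missing
#' data: a missing child invalidates an AND (a complex cannot be bounded by
#' an unknown component) but is simply dropped from an OR.
#'
#' @param node a GPR tree from [parseGpr()], or `NULL`.
#' @param profile an [ExpressionProfile-class].
#' @return `list(mean=, sd=)`, or `NULL` when the value is missing.
#' @examples
#' pr <- newExpressionProfile(c("YJR109C", "YOR303W", "YJL130C"),
#'                            mean = c(0.156, 0.0976, 0.126),
#'                            sd = c(0.083, 0.033, 0.013))
#' evaluateGpr(parseGpr("(YJR109C and YOR303W) or YJL130C"), pr)
#' @export
evaluateGpr <- function(node, profile) {
  if (is.null(node)) return(NULL)
  if (node$kind == "gene") {
    i <- match(node$gene, profile@genes)
    if (is.na(i)) return(NULL)
    return(list(mean = profile@mean[i], sd = profile@sd[i]))
  }
  vals <- lapply(node$children, evaluateGpr, profile = profile)
  if (node$kind == "and") {
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    means <- vapply(vals, `[[`, numeric(1), "mean")
    sds <- vapply(vals, `[[`, numeric(1), "sd")
    cand <- which(means <= min(means))
    pick <- cand[which.min(sds[cand])]
    return(list(mean = means[pick], sd = sds[pick]))
  }
  # OR: drop missing isoenzymes
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!length(vals)) return(NULL)
  means <- vapply(vals, `[[`, numeric(1), "mean")
  sds <- vapply(vals, `[[`, numeric(1), "sd")
  list(mean = sum(means), sd = sqrt(sum(sds^2)))
}

#' Map an expression profile onto a model's reactions
#'
#' Evaluates every reaction's GPR tree against the profile to produce
#' per-reaction targets d_i and uncertainties sigma_i. Reactions without a
#' GPR, or whose required genes are all unmeasured, get `hasData = FALSE`.
#' Sigmas are floored at `sigmaFloor` so the confidence weight 1/sigma stays
#' finite.
#'
#' @param model a [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class].
#' @param sigmaFloor positive floor on sigma (expression units).
#' @return a [ReactionWeights-class].
#' @export
mapExpression <- function(model, profile, sigmaFloor = 1e-6) {
  stopifnot(sigmaFloor > 0)
  n <- length(model@reactionIds)
  d <- rep(NA_real_, n); sigma <- rep(NA_real_, n)
  has <- rep(FALSE, n)
  for (j in seq_len(n)) {
    ev <- evaluateGpr(model@gpr[[j]], profile)
    if (!is.null(ev)) {
      d[j] <- ev$mean
      sigma[j] <- max(ev$sd, sigmaFloor)
      has[j] <- TRUE
    }
  }
  new("ReactionWeights", reactionIds = model@reactionIds,
      d = d, sigma = sigma, hasData = has)
}

#' Write reaction weights as TSV
#'
#' @param weights a [ReactionWeights-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWeights <- function(weights, path) {
  utils::write.table(weightTable(weights), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
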
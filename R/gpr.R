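## GPR Boolean trees. A tree is a plain list: either
##   list(kind = "gene", gene = "YAL060W")
## or
##   list(kind = "and"/"or", children = list(<tree>, <tree>, ...))
## with >= 2 children per internal node (same-operator chains are flattened).

#' Parse a gene-protein-reaction rule string
#'
#' Parses Boolean gene association rules such as
#' `"(YJR109C and YOR303W) or YJL130C"` into a tree of gene leaves and
#' AND/OR nodes. Operators are case-insensitive; `and` binds tighter than
#' `or` (the usual COBRA convention) when parentheses are omitted. An AND
#' node represents an enzyme complex, an OR node a set of isoenzymes.
#'
#' @param rule character scalar; the rule. Empty or all-whitespace rules
#'   (no gene association) return `NULL`.
#' @return a GPR tree (nested list) or `NULL`.
#' @examples
#' parseGpr("(YJR109C and YOR303W) or YJL130C")
#' @export
parseGpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  s <- trimws(rule)
  if (!nzchar(s)) return(NULL)

  toks <- .gpr_tokenize(s, rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$rule <- rule
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("trailing input in GPR rule: ", rule)
  tree
}

.gpr_tokenize <- function(s, rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, s)[[1]]
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  if (!length(toks)) stop("cannot tokenize GPR rule: ", rule)
  toks
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.gpr_next <- function(st) { t <- .gpr_peek(st); st$pos <- st$pos + 1L; t }

.gpr_parse_or <- function(st) {
  kids <- list(.gpr_parse_and(st))
  while (!is.na(t <- .gpr_peek(st)) && tolower(t) == "or") {
    .gpr_next(st)
    kids <- c(kids, list(.gpr_parse_and(st)))
  }
  .gpr_node("or", kids)
}

.gpr_parse_and <- function(st) {
  kids <- list(.gpr_parse_atom(st))
  while (!is.na(t <- .gpr_peek(st)) && tolower(t) == "and") {
    .gpr_next(st)
    kids <- c(kids, list(.gpr_parse_atom(st)))
  }
  .gpr_node("and", kids)
}

.gpr_parse_atom <- function(st) {
  t <- .gpr_next(st)
  if (is.na(t)) stop("empty operand in GPR rule: ", st$rule)
  if (t == "(") {
    inner <- .gpr_parse_or(st)
    if (is.na(cl <- .gpr_next(st)) || cl != ")")
      stop("unbalanced parentheses in GPR rule: ", st$rule)
    return(inner)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop("unexpected token '", t, "' in GPR rule: ", st$rule)
  list(kind = "gene", gene = t)
}

## collapse single-child nodes; flatten nested same-operator children
.gpr_node <- function(kind, kids) {
  if (length(kids) == 1L) return(kids[[1L]])
  flat <- list()
  for (k in kids) {
    if (!is.null(k$kind) && k$kind == kind) flat <- c(flat, k$children)
    else flat <- c(flat, list(k))
  }
  list(kind = kind, children = flat)
}

#' Serialise a GPR tree back to a rule string
#'
#' Produces a canonical, fully parenthesised rule string; re-parsing it
#' returns an identical tree.
#'
#' @param node a GPR tree from [parseGpr()], or `NULL`.
#' @return character scalar, or `""` for `NULL`.
#' @export
gprToString <- function(node) {
  if (is.null(node)) return("")
  if (node$kind == "gene") return(node$gene)
  parts <- vapply(node$children, function(k) {
    s <- gprToString(k)
    if (k$kind != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$kind, " "))
}

#' Genes referenced by a GPR tree
#'
#' @param node a GPR tree or `NULL`.
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gprGenes <- function(node) {
  if (is.null(node)) return(character(0))
  if (node$kind == "gene") return(node$gene)
  unique(unlist(lapply(node$children, gprGenes)))
}
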
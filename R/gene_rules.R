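# Boolean gene-association rules: "gA and (gB or gC)".  Operators are
# case-insensitive; gene ids are any token without whitespace or parentheses.

.gr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# recursive descent; returns list(ast, rest)
.gr_parse_expr <- function(toks) {
  out <- .gr_parse_term(toks)
  node <- out$ast; toks <- out$rest
  while (length(toks) && tolower(toks[1]) == "or") {
    out <- .gr_parse_term(toks[-1])
    node <- list(op = "or", l = node, r = out$ast)
    toks <- out$rest
  }
  list(ast = node, rest = toks)
}

.gr_parse_term <- function(toks) {
  out <- .gr_parse_factor(toks)
  node <- out$ast; toks <- out$rest
  while (length(toks) && tolower(toks[1]) == "and") {
    out <- .gr_parse_factor(toks[-1])
    node <- list(op = "and", l = node, r = out$ast)
    toks <- out$rest
  }
  list(ast = node, rest = toks)
}

.gr_parse_factor <- function(toks) {
  if (!length(toks)) stop("gene rule: unexpected end of expression", call. = FALSE)
  if (toks[1] == "(") {
    out <- .gr_parse_expr(toks[-1])
    if (!length(out$rest) || out$rest[1] != ")")
      stop("gene rule: unbalanced parentheses", call. = FALSE)
    return(list(ast = out$ast, rest = out$rest[-1]))
  }
  if (tolower(toks[1]) %in% c("and", "or", ")"))
    stop("gene rule: unexpected token '", toks[1], "'", call. = FALSE)
  list(ast = list(op = "gene", id = toks[1]), rest = toks[-1])
}

.gr_parse <- function(rule) {
  out <- .gr_parse_expr(.gr_tokenize(rule))
  if (length(out$rest))
    stop("gene rule: trailing tokens '", paste(out$rest, collapse = " "), "'",
         call. = FALSE)
  out$ast
}

.gr_eval <- function(ast, present) {
  switch(ast$op,
         gene = ast$id %in% present,
         and = .gr_eval(ast$l, present) && .gr_eval(ast$r, present),
         or = .gr_eval(ast$l, present) || .gr_eval(ast$r, present))
}

.gr_genes <- function(ast) {
  if (ast$op == "gene") return(ast$id)
  c(.gr_genes(ast$l), .gr_genes(ast$r))
}

#' Genes referenced by a gene rule
#'
#' @param rule a boolean gene-association string (`"gA and (gB or gC)"`).
#' @return character vector of gene ids (empty for `NA`/empty rules).
#' @export
gene_rule_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  unique(.gr_genes(.gr_parse(rule)))
}

#' Evaluate a gene rule against a set of present genes
#'
#' Genes not listed in `present` evaluate `FALSE` (conservative convention
#' for partial ortholog maps).
#'
#' @param rule gene-association string; `NA` or empty returns `NA` (the
#'   reaction is not gene-associated).
#' @param present character vector of genes assumed functional.
#' @return `TRUE`, `FALSE`, or `NA` for non-gene-associated reactions.
#' @export
eval_gene_rule <- function(rule, present) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NA)
  .gr_eval(.gr_parse(rule), present)
}

# substitute mapped gene ids (named chr: reference -> query); unmapped ids kept
.gr_rewrite <- function(rule, map) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(rule)
  toks <- .gr_tokenize(rule)
  out <- vapply(toks, function(tk) {
    if (tk %in% c("(", ")") || tolower(tk) %in% c("and", "or")) tk
    else if (tk %in% names(map)) unname(map[tk])
    else tk
  }, character(1))
  # re-assemble with spaces, tightening parentheses
  s <- paste(out, collapse = " ")
  s <- gsub("\\( ", "(", s)
  gsub(" \\)", ")", s)
}
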
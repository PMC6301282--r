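# Gene-protein-reaction rules: boolean expressions over gene ids with
# `and` (enzyme complex) and `or` (isozymes), e.g. "gA and (gB or gC)".

tokenize_gpr <- function(gpr) {
  gpr <- gsub("\\(", " ( ", gsub("\\)", " ) ", gpr))
  toks <- strsplit(trimws(gpr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule into an expression tree
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene | '(' expr ')'`. Operators are case-insensitive; gene ids
#' are any other token.
#'
#' @param gpr the rule string.
#' @return a nested list tree with nodes `list(op = "and"/"or", args = ...)`
#'   and leaves of class character (gene ids).
#' @export
parse_gpr <- function(gpr) {
  toks <- tokenize_gpr(gpr)
  if (!length(toks)) stop("empty GPR rule", call. = FALSE)
  pos <- 1
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { tk <- toks[pos]; pos <<- pos + 1; tk }
  is_op <- function(tk, op) !is.na(tk) && tolower(tk) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) { advance(); args <- c(args, list(parse_term())) }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) { advance(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed GPR rule: '", gpr, "'", call. = FALSE)
    if (tk == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")"))
        stop("malformed GPR rule (unbalanced parentheses): '", gpr, "'",
             call. = FALSE)
      advance()
      return(e)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or"))
      stop("malformed GPR rule: '", gpr, "'", call. = FALSE)
    advance()
  }
  tree <- parse_expr()
  if (pos <= length(toks))
    stop("malformed GPR rule (trailing tokens): '", gpr, "'", call. = FALSE)
  tree
}

#' Gene ids referenced by a GPR rule
#' @param gpr the rule string.
#' @return character vector of unique gene ids.
#' @export
gpr_genes <- function(gpr) {
  toks <- tokenize_gpr(gpr)
  unique(toks[!(tolower(toks) %in% c("and", "or", "(", ")")) &
                !toks %in% c("(", ")")])
}

eval_gpr <- function(tree, theta, missing_theta = 1) {
  if (is.character(tree)) {
    if (tree %in% names(theta)) return(unname(theta[[tree]]))
    return(missing_theta)
  }
  vals <- vapply(tree$args, eval_gpr, 0, theta = theta,
                 missing_theta = missing_theta)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Aggregate gene expression onto a reaction through its GPR rule
#'
#' AND nodes (subunits of a complex) take the minimum expression of their
#' operands; OR nodes (isozymes) take the maximum. Genes absent from the
#' profile contribute `missing_theta` (default 1, the reference level).
#'
#' @param gpr GPR rule string.
#' @param profile named numeric vector of normalised expression levels theta.
#' @param missing_theta value used for genes absent from `profile`.
#' @return the reaction-level expression theta.
#' @export
reaction_expression <- function(gpr, profile, missing_theta = 1) {
  eval_gpr(parse_gpr(gpr), profile, missing_theta)
}
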
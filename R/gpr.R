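#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers describing which
#' gene products a reaction needs: `and` joins subunits of an enzyme complex
#' (all required), `or` joins isozymes (any suffices). Rules are stored as
#' strings in the model and parsed on demand into an expression tree.
#'
#' The grammar is parenthesized infix with case-insensitive `and` / `or`;
#' `and` binds tighter than `or`, so `a and b or c` means `(a and b) or c`.
#' An empty rule (no gene association) always evaluates to active.
#'
#' @param rule a GPR rule string, e.g. `"(g1 and g2) or g3"`; `NA` or `""`
#'   denote the empty rule.
#' @return `parse_gpr()` returns the expression tree: `NULL` for the empty
#'   rule, a length-one character vector for a single gene, or a list with
#'   elements `op` (`"and"` or `"or"`) and `args` (list of subtrees).
#' @examples
#' tree <- parse_gpr("(g1 and g2) or g3")
#' evaluate_gpr(tree, knocked_out = c("g1", "g3"))
#' gpr_genes(tree)
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", rule,
         call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of input", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("malformed GPR rule: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' @rdname parse_gpr
#' @param tree a parsed GPR expression tree (or a rule string, which is
#'   parsed first).
#' @param knocked_out character vector of gene ids treated as deleted.
#' @return `evaluate_gpr()` returns `TRUE` if the reaction remains
#'   catalyzable with the given genes knocked out.
#' @export
evaluate_gpr <- function(tree, knocked_out = character()) {
  if (is.character(tree) && length(tree) == 1L && !tree_is_gene(tree)) {
    tree <- parse_gpr(tree)
  }
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% knocked_out))
  vals <- vapply(tree$args, evaluate_gpr, logical(1), knocked_out = knocked_out)
  if (tree$op == "and") all(vals) else any(vals)
}

# a bare string is a gene leaf unless it is empty or contains rule syntax
tree_is_gene <- function(x) {
  !is.na(x) && nzchar(x) && !grepl("[()]|\\s", x)
}

#' @rdname parse_gpr
#' @return `gpr_genes()` returns the sorted unique gene ids in the rule.
#' @export
gpr_genes <- function(tree) {
  if (is.character(tree) && length(tree) == 1L && !tree_is_gene(tree)) {
    tree <- parse_gpr(tree)
  }
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  sort(unique(unlist(lapply(tree$args, gpr_genes))))
}

#' @rdname parse_gpr
#' @return `deparse_gpr()` returns a canonical rule string that reparses to
#'   an identical tree (parse-print-parse is a fixpoint).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    # 'and' binds tighter: parenthesize an 'or' child under an 'and' node
    if (tree$op == "and" && is.list(a) && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
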
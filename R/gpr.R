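# Gene-protein-reaction (GPR) boolean rules.
#
# A rule is stored as a tree: a character scalar is a gene leaf, an internal
# node is list(op = "and"|"or", args = list(...)), and NULL is the empty rule
# (no gene association; such reactions cannot be disabled by gene knockout).
# Grammar for the text form: case-insensitive AND/OR keywords, parentheses,
# bare gene-id tokens; AND binds tighter than OR.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR string such as `"G1 and (G2 or G3)"` into the
#' package's rule tree. `OR` joins isozymes or redundant alleles (any one
#' gene suffices), `AND` joins subunits of a complex (all genes required).
#'
#' @param text GPR string; `""`, `NA` or `NULL` give the empty rule.
#' @return A rule tree (`NULL` for the empty rule).
#' @export
#' @examples
#' parse_gpr("G1 and (G2 or G3)")
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  rule <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", text)
  rule
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, gregexpr(pat, text))[[1]]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

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
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of input")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR rule: missing closing parenthesis")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("malformed GPR rule: unexpected token '", tk, "'")
  st$pos <- st$pos + 1L
  tk
}

#' Serialise a GPR rule tree to text
#'
#' @param rule A rule tree as returned by [parse_gpr()].
#' @return A single string; `""` for the empty rule.
#' @export
gpr_to_string <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  parts <- vapply(rule$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Genes appearing in a GPR rule
#'
#' @param rule A rule tree.
#' @return Character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Substitutes `FALSE` for knocked-out genes and `TRUE` for all others, then
#' evaluates the boolean tree. The empty rule evaluates `TRUE`: a reaction
#' with no gene association cannot be disabled through genes.
#'
#' @param rule A rule tree (or GPR string, parsed on the fly).
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return `TRUE` if the reaction retains catalytic support, else `FALSE`.
#' @export
#' @examples
#' evaluate_gpr(parse_gpr("A or B"), "A")        # TRUE: isozyme remains
#' evaluate_gpr(parse_gpr("A and B"), "A")       # FALSE: complex broken
evaluate_gpr <- function(rule, knocked_out = character(0)) {
  if (is.character(rule) && length(rule) == 1L && grepl("[()[:space:]]", rule))
    rule <- parse_gpr(rule)
  gpr_eval_tree(rule, knocked_out)
}

gpr_eval_tree <- function(rule, ko) {
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(!(rule %in% ko))
  vals <- vapply(rule$args, gpr_eval_tree, logical(1), ko = ko)
  if (rule$op == "and") all(vals) else any(vals)
}

# substitute each leaf of gene `gene` by (gene OR allele); no-op on other leaves
gpr_augment_tree <- function(rule, gene, allele) {
  if (is.null(rule)) return(NULL)
  if (is.character(rule)) {
    if (rule == gene) return(list(op = "or", args = list(gene, allele)))
    return(rule)
  }
  rule$args <- lapply(rule$args, gpr_augment_tree, gene = gene, allele = allele)
  rule
}

# TRUE if `allele` already appears as an OR-partner of `gene` somewhere
gpr_has_or_pair <- function(rule, gene, allele) {
  if (is.null(rule) || is.character(rule)) return(FALSE)
  if (rule$op == "or") {
    leaves <- unlist(Filter(is.character, rule$args))
    if (gene %in% leaves && allele %in% leaves) return(TRUE)
  }
  any(vapply(rule$args, gpr_has_or_pair, logical(1), gene = gene, allele = allele))
}
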
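# Gene-protein-reaction (GPR) rule handling.
#
# A GPR is a boolean expression over gene identifiers in which 'and' denotes
# a protein complex (all subunits required) and 'or' denotes isozymes
# (alternative enzymes).  Rules are stored as strings; the parser below
# produces a nested list with elements list(op = "and"|"or", args = ...) and
# character leaves, and gpr_to_dnf() flattens a rule to its disjunctive
# normal form: a list of character vectors, each vector one 'and'-complex.

gpr_tokenize <- function(x) {
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule string
#'
#' @param x a GPR string, e.g. `"(g1 and g2) or g3"`. 'and'/'or' are matched
#'   case-insensitively; empty or all-whitespace strings give `NULL`.
#' @return `NULL`, a gene id (character scalar), or a nested
#'   `list(op = , args = )` tree.
#' @export
gpr_parse <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule: ", sQuote(x), call. = FALSE)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("unbalanced parentheses in GPR rule: ", sQuote(x), call. = FALSE)
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule: ", sQuote(x), call. = FALSE)
    advance()
  }

  node <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: ", sQuote(x), call. = FALSE)
  node
}

#' Convert a GPR rule to disjunctive normal form
#'
#' @param x a GPR string or parsed tree.
#' @param max_conjuncts expansion cap; rules whose DNF would exceed this many
#'   'and'-complexes raise an error.
#' @return a list of character vectors; each vector is one complex (the genes
#'   joined by 'and'), the list elements are the isozyme alternatives.
#'   `NULL`/empty rules give an empty list.
#' @export
gpr_to_dnf <- function(x, max_conjuncts = 64L) {
  node <- if (is.character(x) && length(x) == 1L && !is.list(x)) gpr_parse(x) else x
  if (is.null(node)) return(list())
  rec <- function(nd) {
    if (is.character(nd)) return(list(nd))
    if (nd$op == "or") {
      out <- list()
      for (a in nd$args) out <- c(out, rec(a))
      if (length(out) > max_conjuncts)
        stop("GPR DNF expansion exceeds ", max_conjuncts, " conjuncts", call. = FALSE)
      return(out)
    }
    # 'and': cartesian product of the argument DNFs
    parts <- lapply(nd$args, rec)
    out <- list(character(0))
    for (p in parts) {
      out <- unlist(lapply(out, function(pref) {
        lapply(p, function(conj) union(pref, conj))
      }), recursive = FALSE)
      if (length(out) > max_conjuncts)
        stop("GPR DNF expansion exceeds ", max_conjuncts, " conjuncts", call. = FALSE)
    }
    out
  }
  lapply(rec(node), function(g) sort(unique(g)))
}

#' Genes referenced by a GPR rule
#' @param x a GPR string or parsed tree.
#' @return character vector of gene ids (unique, sorted).
#' @export
gpr_genes <- function(x) {
  node <- if (is.character(x) && !is.list(x)) gpr_parse(x) else x
  if (is.null(node)) return(character(0))
  rec <- function(nd) {
    if (is.character(nd)) return(nd)
    unlist(lapply(nd$args, rec))
  }
  sort(unique(rec(node)))
}

#' Render a DNF conjunct list back to a GPR string
#' @param dnf a list of character vectors as returned by [gpr_to_dnf()].
#' @return a GPR string ('' for an empty list).
#' @export
gpr_deparse_dnf <- function(dnf) {
  if (!length(dnf)) return("")
  terms <- vapply(dnf, function(g) {
    if (length(g) == 1L) g else paste0("(", paste(g, collapse = " and "), ")")
  }, character(1))
  paste(terms, collapse = " or ")
}
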
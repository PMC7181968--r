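#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers stating which gene
#' combinations enable a reaction: \code{and} denotes an enzyme complex (all
#' subunits required), \code{or} denotes isozymes (any one suffices). The
#' grammar accepts case-insensitive \code{and}/\code{or}, parentheses, and
#' gene ids as arbitrary non-whitespace tokens; \code{and} binds tighter than
#' \code{or}. An empty string (or \code{NA}) denotes a spontaneous reaction.
#'
#' @param text GPR rule string, e.g. \code{"g1 and (g2 or g3)"}.
#' @return A parse tree: \code{NULL} for an empty rule, or a nested list with
#'   \code{op} one of \code{"gene"}, \code{"and"}, \code{"or"}; gene nodes
#'   carry \code{gene}, operator nodes carry \code{args} (a list of subtrees).
#' @seealso [evaluate_gpr()], [gpr_genes()], [gpr_to_dnf()]
#' @export
#' @examples
#' ast <- parse_gpr("g1 and (g2 or g3)")
#' gpr_genes(ast)
#' evaluate_gpr(ast, knocked_out = "g2")
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule: unexpected token '", st$toks[st$pos],
         "' in \"", text, "\"", call. = FALSE)
  }
  ast
}

gpr_tokenize <- function(text) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", text))
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of input", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR rule: missing ')'", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("malformed GPR rule: unexpected token '", tk, "'", call. = FALSE)
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Evaluate a GPR rule under a gene knockout
#'
#' A gene leaf evaluates to \code{TRUE} iff the gene is not knocked out;
#' \code{and}/\code{or} follow boolean semantics; an empty rule (spontaneous
#' reaction) is always \code{TRUE}.
#'
#' @param rule Parse tree from [parse_gpr()] (or a rule string).
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return Logical scalar: is the reaction still catalyzable?
#' @export
evaluate_gpr <- function(rule, knocked_out = character()) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(TRUE)
  switch(rule$op,
    gene = !(rule$gene %in% knocked_out),
    and  = all(vapply(rule$args, evaluate_gpr, logical(1), knocked_out = knocked_out)),
    or   = any(vapply(rule$args, evaluate_gpr, logical(1), knocked_out = knocked_out)),
    stop("invalid GPR node op: ", rule$op)
  )
}

#' Genes referenced by a GPR rule
#'
#' @param rule Parse tree from [parse_gpr()] (or a rule string).
#' @return Sorted character vector of distinct gene ids (empty for a
#'   spontaneous reaction).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(character())
  if (rule$op == "gene") return(rule$gene)
  sort(unique(unlist(lapply(rule$args, gpr_genes))))
}

#' Convert a GPR rule to disjunctive normal form
#'
#' Returns the rule as a list of conjunctions, each a sorted character vector
#' of gene ids: the reaction is active iff, for at least one conjunction, all
#' of its genes are present. Duplicate conjunctions are removed. The DNF of
#' dense and/or nests can grow combinatorially, so the expansion is capped.
#'
#' @param rule Parse tree from [parse_gpr()] (or a rule string).
#' @param max_disjuncts Cap on the number of conjunctions; exceeding it
#'   returns \code{NULL} so callers can fall back to direct rule evaluation.
#' @return List of character vectors (one per disjunct), \code{list()} for an
#'   empty rule, or \code{NULL} if the cap was exceeded.
#' @export
gpr_to_dnf <- function(rule, max_disjuncts = 64L) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(list())
  dnf <- gpr_dnf_rec(rule, max_disjuncts)
  if (is.null(dnf)) return(NULL)
  keys <- vapply(dnf, paste, character(1), collapse = "\r")
  dnf[!duplicated(keys)]
}

gpr_dnf_rec <- function(node, cap) {
  if (node$op == "gene") return(list(node$gene))
  parts <- lapply(node$args, gpr_dnf_rec, cap = cap)
  if (any(vapply(parts, is.null, logical(1)))) return(NULL)
  if (node$op == "or") {
    out <- do.call(c, parts)
    if (length(out) > cap) return(NULL)
    return(out)
  }
  # and: cross product of the disjunct lists
  out <- list(character())
  for (p in parts) {
    nxt <- vector("list", length(out) * length(p))
    k <- 0L
    for (a in out) for (b in p) {
      k <- k + 1L
      nxt[[k]] <- sort(unique(c(a, b)))
    }
    if (k > cap) return(NULL)
    out <- nxt
  }
  out
}

#' Render a GPR parse tree back to a rule string
#'
#' @param rule Parse tree from [parse_gpr()].
#' @return Rule string (empty string for a spontaneous reaction).
#' @export
deparse_gpr <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$op == "gene") return(rule$gene)
  sep <- if (rule$op == "and") " and " else " or "
  parts <- vapply(rule$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.null(a$op) && a$op != "gene" && a$op != rule$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = sep)
}
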
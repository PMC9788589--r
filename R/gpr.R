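#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `AND`
#' (enzyme complexes) and `OR` (isozymes), case-insensitive, with
#' parentheses. `AND` binds tighter than `OR`, so `"G1 AND G2 OR G3"`
#' parses as `(G1 AND G2) OR G3`.
#'
#' @param rule character scalar. An empty string (or `NA`) denotes the
#'   absence of a rule and returns `NULL`.
#' @return An object of class `gpr_tree`: either a gene leaf
#'   (`list(gene = <id>)`) or an operator node
#'   (`list(op = "AND"|"OR", children = list(...))`), or `NULL` for an
#'   empty rule.
#' @export
#' @examples
#' parse_gpr("(G1 AND G2) OR G3")
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L

  tree <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    stop(sprintf("GPR parse error at character %d of %s: unexpected '%s'",
                 tk$at, sQuote(rule), tk$text), call. = FALSE)
  }
  tree
}

# tokenizer: genes, AND/OR (case-insensitive), parentheses; records positions
gpr_tokenize <- function(rule) {
  toks <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(rule, i, n), regexpr("^[A-Za-z0-9_.:-]+", substr(rule, i, n)))
    if (length(m) == 0L) {
      stop(sprintf("GPR parse error at character %d of %s: unexpected '%s'",
                   i, sQuote(rule), ch), call. = FALSE)
    }
    word <- m[[1]]
    up <- toupper(word)
    type <- if (up == "AND") "AND" else if (up == "OR") "OR" else "GENE"
    toks[[length(toks) + 1L]] <- list(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, rule) {
  children <- list(gpr_parse_and(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "OR") break
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_and(st, rule)
  }
  if (length(children) == 1L) children[[1L]]
  else structure(list(op = "OR", children = children), class = "gpr_tree")
}

gpr_parse_and <- function(st, rule) {
  children <- list(gpr_parse_atom(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "AND") break
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_atom(st, rule)
  }
  if (length(children) == 1L) children[[1L]]
  else structure(list(op = "AND", children = children), class = "gpr_tree")
}

gpr_parse_atom <- function(st, rule) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error at character %d of %s: dangling operator",
                 nchar(rule) + 1L, sQuote(rule)), call. = FALSE)
  }
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, rule)
    close_tk <- gpr_peek(st)
    if (is.null(close_tk) || close_tk$type != ")") {
      stop(sprintf("GPR parse error at character %d of %s: unbalanced parenthesis",
                   tk$at, sQuote(rule)), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "GENE") {
    st$pos <- st$pos + 1L
    return(structure(list(gene = tk$text), class = "gpr_tree"))
  }
  stop(sprintf("GPR parse error at character %d of %s: unexpected '%s'",
               tk$at, sQuote(rule), tk$text), call. = FALSE)
}

#' Evaluate a GPR tree against gene expression values
#'
#' `AND` takes the minimum of its children (a complex is limited by its
#' scarcest subunit), `OR` the maximum (any isozyme suffices); a leaf
#' evaluates to the gene's value. Genes missing from `gene_values`
#' evaluate to 0 with a warning (absent evidence excludes).
#'
#' @param tree a `gpr_tree` from [parse_gpr()] (not `NULL`).
#' @param gene_values named non-negative numeric vector of expression
#'   values (e.g. TPM).
#' @return non-negative numeric scalar.
#' @export
evaluate_gpr <- function(tree, gene_values) {
  if (is.null(tree)) stop("cannot evaluate an empty GPR rule", call. = FALSE)
  missing <- setdiff(gpr_genes(tree), names(gene_values))
  if (length(missing) > 0L) {
    warning(sprintf("genes missing from expression, scored as 0: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  gpr_eval_rec(tree, gene_values)
}

gpr_eval_rec <- function(node, gene_values) {
  if (!is.null(node$gene)) {
    v <- unname(gene_values[node$gene])
    if (length(v) == 0L || is.na(v)) return(0)
    return(as.numeric(v))
  }
  vals <- vapply(node$children, gpr_eval_rec, numeric(1), gene_values = gene_values)
  if (node$op == "AND") min(vals) else max(vals)
}

#' List the genes referenced by a GPR tree
#'
#' @param tree a `gpr_tree` or `NULL`.
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Render a GPR tree back to rule text
#'
#' Unparsing then reparsing is idempotent up to whitespace. Child
#' subexpressions are parenthesized whenever their operator differs from
#' the parent's.
#'
#' @param tree a `gpr_tree` or `NULL` (rendered as `""`).
#' @return character scalar.
#' @export
format_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$children, function(ch) {
    txt <- format_gpr(ch)
    if (is.null(ch$gene) && ch$op != tree$op) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Canonicalize a GPR rule string
#'
#' Produces a normal form under which logically identical rules compare
#' equal as strings: operators uppercased, nested same-operator nodes
#' flattened, duplicate operands dropped, and operands sorted
#' lexicographically (so `"G1 AND G2"` and `"G2 AND G1"` canonicalize
#' identically). Used when counting unique gene rules.
#'
#' @param rule GPR rule string (may be empty).
#' @return canonical rule string (empty input stays empty).
#' @export
canonical_gpr <- function(rule) {
  tree <- parse_gpr(rule)
  if (is.null(tree)) return("")
  format_gpr(gpr_canon_rec(tree))
}

gpr_canon_rec <- function(node) {
  if (!is.null(node$gene)) return(node)
  kids <- list()
  for (ch in node$children) {
    cc <- gpr_canon_rec(ch)
    if (is.null(cc$gene) && cc$op == node$op) kids <- c(kids, cc$children)
    else kids[[length(kids) + 1L]] <- cc
  }
  keys <- vapply(kids, format_gpr, character(1))
  kids <- kids[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  kids <- kids[order(keys, method = "radix")]
  if (length(kids) == 1L) return(kids[[1L]])
  structure(list(op = node$op, children = kids), class = "gpr_tree")
}
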
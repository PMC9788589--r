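#' Assemble a gene x sample expression matrix
#'
#' @param counts non-negative numeric matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids). May hold raw
#'   counts or precomputed TPM.
#' @param sample_state named character vector mapping every sample to a
#'   disease-state label.
#' @param lengths optional named numeric vector of effective gene lengths
#'   (bases); required for TPM normalization of raw counts.
#' @param model optional `metabolic_model`; if given, the overlap between
#'   expression genes and model genes is checked (warning when they share
#'   less than half of the model's genes).
#' @return object of class `expression_matrix` with elements `counts`,
#'   `sample_state`, `lengths`.
#' @export
expression_matrix <- function(counts, sample_state, lengths = NULL, model = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("expression matrix has negative entries", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  }
  unmapped <- setdiff(colnames(counts), names(sample_state))
  if (length(unmapped)) stop("samples without a state label: ",
                             paste(unmapped, collapse = ", "), call. = FALSE)
  if (!is.null(lengths)) {
    missing_len <- setdiff(rownames(counts), names(lengths))
    if (length(missing_len)) stop("genes without a length: ",
                                  paste(utils::head(missing_len, 5), collapse = ", "),
                                  call. = FALSE)
  }
  if (!is.null(model)) {
    shared <- intersect(rownames(counts), model$genes)
    if (length(shared) < 0.5 * length(model$genes)) {
      warning(sprintf("only %d of %d model genes found in expression data",
                      length(shared), length(model$genes)), call. = FALSE)
    }
  }
  structure(list(counts = counts,
                 sample_state = sample_state[colnames(counts)],
                 lengths = lengths),
            class = "expression_matrix")
}

#' TPM-normalize a raw count matrix
#'
#' Per sample, `tpm_g = 1e6 * (counts_g / length_g) / sum_k(counts_k /
#' length_k)`, so every sample column sums to one million. An all-zero
#' sample yields an all-zero column with a warning.
#'
#' @param counts gene x sample non-negative matrix with gene rownames.
#' @param lengths named numeric vector of effective gene lengths (> 0).
#' @return matrix of TPM values, same dimnames as `counts`.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  len <- lengths[rownames(counts)]
  bad <- rownames(counts)[is.na(len) | len <= 0]
  if (length(bad)) stop("genes with missing/non-positive length: ",
                        paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  rates <- counts / as.numeric(len)
  totals <- colSums(rates)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero samples left as zero columns: ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1
  }
  sweep(rates, 2, totals, "/") * 1e6
}

#' Aggregate per-sample TPM into per-state profiles
#'
#' The extraction threshold rule uses the per-gene *maximum* TPM within a
#' state (default); the flux-prediction scoring conventionally uses the
#' state *mean*. Both are exposed.
#'
#' @param tpm gene x sample TPM matrix.
#' @param sample_state named character vector, sample -> state.
#' @param method `"max"` (default) or `"mean"`.
#' @param states optional subset of states (error if unknown).
#' @return named list of `state_profile` objects (`state`, `gene_values`).
#' @export
aggregate_states <- function(tpm, sample_state, method = c("max", "mean"),
                             states = NULL) {
  method <- match.arg(method)
  sample_state <- sample_state[colnames(tpm)]
  if (is.null(states)) states <- unique(unname(sample_state))
  unknown <- setdiff(states, sample_state)
  if (length(unknown)) stop("unknown state labels: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  fn <- if (method == "max") function(m) apply(m, 1, max) else rowMeans
  out <- lapply(states, function(s) {
    cols <- names(sample_state)[sample_state == s]
    vals <- fn(tpm[, cols, drop = FALSE])
    structure(list(state = s, gene_values = vals), class = "state_profile")
  })
  stats::setNames(out, states)
}

#' Score model reactions through their GPR rules
#'
#' For every reaction with a GPR rule, the score `g_j` is the rule
#' evaluated against the state profile (AND = min, OR = max). Reactions
#' with an empty rule are collected in `no_gpr` and carry no score.
#'
#' @param model a `metabolic_model`.
#' @param profile a `state_profile` from [aggregate_states()], or any
#'   named numeric vector of per-gene values.
#' @return object of class `reaction_scores`: `state`, `scores` (named,
#'   ruled reactions only), `no_gpr` (character).
#' @export
score_reactions <- function(model, profile) {
  if (inherits(profile, "state_profile")) {
    state <- profile$state
    gene_values <- profile$gene_values
  } else {
    state <- NA_character_
    gene_values <- profile
  }
  rules <- model$reactions$gpr
  has_rule <- nzchar(rules)
  missing <- setdiff(
    unique(unlist(lapply(rules[has_rule], function(g) gpr_genes(parse_gpr(g))))),
    names(gene_values))
  if (length(missing)) {
    warning(sprintf("%d model genes absent from expression profile, scored as 0",
                    length(missing)), call. = FALSE)
  }
  scores <- vapply(which(has_rule), function(i) {
    gpr_eval_rec(parse_gpr(rules[i]), gene_values)
  }, numeric(1))
  names(scores) <- model$reactions$id[has_rule]
  structure(list(state = state, scores = scores,
                 no_gpr = model$reactions$id[!has_rule]),
            class = "reaction_scores")
}

#' Read a numeric TSV table (genes/reactions in rows, header of ids)
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a numeric matrix as TSV with a leading id column
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param id_col header of the row-id column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column TSV as a named vector (first column = names)
#' @param path file path.
#' @param numeric coerce values to numeric.
#' @return named vector.
#' @export
read_tsv_map <- function(path, numeric = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- df[[2]]
  if (numeric) vals <- as.numeric(vals)
  stats::setNames(vals, df[[1]])
}
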
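#' Binary reaction-presence matrix across context models
#'
#' One column per model over the union of their reaction sets: 1 where the
#' model contains the reaction, 0 where it does not.
#'
#' @param models list of >= 2 `context_model`s sharing a parent.
#' @return binary matrix, reactions x models, class `presence_matrix`.
#' @export
presence_matrix <- function(models) {
  stopifnot(length(models) >= 2L)
  parents <- unique(vapply(models, function(m) m$parent_id, character(1)))
  if (length(parents) > 1L) {
    stop("models come from different parents: ",
         paste(parents, collapse = ", "), call. = FALSE)
  }
  names <- vapply(models, function(m) m$state, character(1))
  union_rx <- unique(unlist(lapply(models, function(m) m$kept_reactions)))
  mat <- vapply(models, function(m) as.integer(union_rx %in% m$kept_reactions),
                integer(length(union_rx)))
  dimnames(mat) <- list(union_rx, names)
  structure(mat, class = c("presence_matrix", class(mat)))
}

#' Hamming similarity between context models
#'
#' `similarity(a, b) = 1 - (disagreeing reactions) / (total reactions)`
#' over the presence matrix's rows (the union reaction set), so identical
#' models score 1 and fully disjoint ones 0.
#'
#' @param mat a `presence_matrix`.
#' @return symmetric model x model similarity matrix with unit diagonal.
#' @export
hamming_similarity <- function(mat) {
  stopifnot(nrow(mat) > 0L)
  m <- ncol(mat)
  out <- matrix(1, m, m, dimnames = list(colnames(mat), colnames(mat)))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a < b) {
      s <- 1 - sum(mat[, a] != mat[, b]) / nrow(mat)
      out[a, b] <- s; out[b, a] <- s
    }
  }
  out
}

#' Rank context models by structural size
#'
#' Ranks models by number of reactions, metabolites, genes, and unique
#' gene rules (after GPR canonicalization, so operand order does not
#' matter). Rank 1 = largest; ties share the mean rank.
#'
#' @param models list of >= 2 `context_model`s.
#' @param parent their parent `metabolic_model`.
#' @return data.frame with the four counts and four rank columns, one row
#'   per model.
#' @export
rank_models <- function(models, parent) {
  stopifnot(length(models) >= 2L)
  rows <- lapply(models, function(m) {
    sub <- context_submodel(m, parent)
    rules <- sub$reactions$gpr[nzchar(sub$reactions$gpr)]
    data.frame(model = m$state,
               reactions = nrow(sub$reactions),
               metabolites = nrow(sub$metabolites),
               genes = length(sub$genes),
               unique_gene_rules = length(unique(vapply(rules, canonical_gpr,
                                                        character(1)))),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (col in c("reactions", "metabolites", "genes", "unique_gene_rules")) {
    df[[paste0("rank_", col)]] <- rank(-df[[col]], ties.method = "average")
  }
  df
}

#' Flag subsystems with divergent reaction coverage across models
#'
#' Per subsystem, counts reactions per model and flags the subsystem when
#' some model pair differs by more than `pct` percent relative to the
#' larger count (`|a-b| / max(a,b) > pct/100`; pairs with both counts zero
#' are skipped). Also reports the number of reactions common to all
#' models per subsystem. Sorted by total subsystem size (descending).
#'
#' @param models list of >= 2 `context_model`s.
#' @param parent their parent `metabolic_model`.
#' @param pct percent difference threshold (default 10).
#' @return data.frame: subsystem, per-model count columns, `common`
#'   (reactions in every model), `max_rel_diff_pct`, `flagged`.
#' @export
differential_subsystems <- function(models, parent, pct = 10) {
  subsys <- stats::setNames(parent$reactions$subsystem, parent$reactions$id)
  all_subsys <- sort(unique(parent$reactions$subsystem))
  model_names <- vapply(models, function(m) m$state, character(1))
  counts <- sapply(models, function(m) {
    tab <- table(factor(subsys[m$kept_reactions], levels = all_subsys))
    as.integer(tab)
  })
  dimnames(counts) <- list(all_subsys, model_names)
  common <- vapply(all_subsys, function(ss) {
    rx_ss <- names(subsys)[subsys == ss]
    length(Reduce(intersect, lapply(models, function(m)
      intersect(m$kept_reactions, rx_ss))))
  }, integer(1))
  rel <- apply(counts, 1, function(cnt) {
    best <- 0
    for (a in seq_along(cnt)) for (b in seq_along(cnt)) {
      if (a < b && max(cnt[a], cnt[b]) > 0) {
        best <- max(best, abs(cnt[a] - cnt[b]) / max(cnt[a], cnt[b]))
      }
    }
    best
  })
  df <- data.frame(subsystem = all_subsys, counts, check.names = FALSE,
                   common = common,
                   max_rel_diff_pct = 100 * rel,
                   flagged = rel > pct / 100,
                   stringsAsFactors = FALSE)
  df[order(-rowSums(counts)), , drop = FALSE]
}

#' Gene-rule drill-down for divergent subsystems
#'
#' Collects the reactions in the given subsystems that are *not* common to
#' all models, collapses them to unique canonical gene rules, and reports
#' per-model reaction counts per rule together with the z-scored (across
#' states) expression of each rule's genes.
#'
#' @param models list of `context_model`s.
#' @param parent their parent `metabolic_model`.
#' @param subsystems subsystem labels to drill into (typically the flagged
#'   rows of [differential_subsystems()]); must exist in the parent.
#' @param state_profiles optional named list of `state_profile`s (for the
#'   z-scored expression block; omitted when `NULL`).
#' @return list: `rules` (data.frame: rule, n_reactions, per-model count
#'   columns), `no_gpr_reactions` (differing reactions without a rule),
#'   `gene_zscores` (gene x state matrix or `NULL`), and scalar counts
#'   `n_differing`, `n_with_rules`, `n_unique_rules`.
#' @export
gene_rule_drilldown <- function(models, parent, subsystems,
                                state_profiles = NULL) {
  unknown <- setdiff(subsystems, parent$reactions$subsystem)
  if (length(unknown)) stop("subsystems absent from parent model: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  rx_pool <- parent$reactions$id[parent$reactions$subsystem %in% subsystems]
  in_any <- rx_pool[rx_pool %in% unlist(lapply(models, function(m) m$kept_reactions))]
  in_all <- Reduce(intersect, lapply(models, function(m)
    intersect(m$kept_reactions, rx_pool)))
  differing <- setdiff(in_any, in_all)
  gpr_map <- stats::setNames(parent$reactions$gpr, parent$reactions$id)
  rules_raw <- gpr_map[differing]
  with_rules <- differing[nzchar(rules_raw)]
  canon <- vapply(gpr_map[with_rules], canonical_gpr, character(1))
  model_names <- vapply(models, function(m) m$state, character(1))

  uniq <- sort(unique(canon))
  per_model <- sapply(models, function(m) {
    vapply(uniq, function(rule) {
      sum(canon == rule & with_rules %in% m$kept_reactions)
    }, integer(1))
  })
  if (length(uniq) == 1L) per_model <- matrix(per_model, nrow = 1)
  dimnames(per_model) <- list(uniq, model_names)
  rules_df <- data.frame(rule = uniq,
                         n_reactions = as.integer(table(factor(canon, levels = uniq))),
                         per_model, check.names = FALSE,
                         stringsAsFactors = FALSE)

  gene_z <- NULL
  if (!is.null(state_profiles) && length(uniq) > 0L) {
    genes <- unique(unlist(lapply(uniq, function(r) gpr_genes(parse_gpr(r)))))
    expr <- sapply(state_profiles, function(p) {
      v <- p$gene_values[genes]
      v[is.na(v)] <- 0
      v
    })
    if (length(genes) == 1L) expr <- matrix(expr, nrow = 1)
    dimnames(expr) <- list(genes, names(state_profiles))
    gene_z <- t(apply(expr, 1, zscore_safe))
    dimnames(gene_z) <- dimnames(expr)
  }
  list(rules = rules_df, no_gpr_reactions = setdiff(differing, with_rules),
       gene_zscores = gene_z,
       n_differing = length(differing),
       n_with_rules = length(with_rules),
       n_unique_rules = length(uniq))
}

# z-score a vector; zero-variance input maps to zeros
zscore_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
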
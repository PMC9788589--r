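#' Sum flux magnitudes per subsystem and state
#'
#' Per state, the fluxes of each subsystem's reactions are summed as
#' magnitudes (`|v|`; reversible-flux sign is a solver convention). A
#' signed sum is available via `signed = TRUE`.
#'
#' @param flux_table reactions x states numeric matrix (rownames =
#'   reaction ids), e.g. from [measurable_fluxes()].
#' @param model the parent `metabolic_model` supplying subsystem labels.
#' @param signed sum signed fluxes instead of magnitudes.
#' @return list: `sums` (subsystem x state matrix), `counts` (reactions
#'   per subsystem in the table).
#' @export
subsystem_flux_sums <- function(flux_table, model, signed = FALSE) {
  unknown <- setdiff(rownames(flux_table), model$reactions$id)
  if (length(unknown)) stop("unknown reactions in flux table: ",
                            paste(utils::head(unknown, 5), collapse = ", "),
                            call. = FALSE)
  subsys <- stats::setNames(model$reactions$subsystem, model$reactions$id)
  labels <- subsys[rownames(flux_table)]
  vals <- if (signed) flux_table else abs(flux_table)
  sums <- rowsum(vals, group = labels)
  counts <- table(labels)
  list(sums = sums, counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Midrank handling of ties; the p-value is exact (distribution-based)
#' when `n + m <= 16` with no ties, and uses the normal approximation with
#' continuity and tie correction otherwise — the screening convention for
#' the pairwise state comparisons.
#'
#' @param x,y numeric samples (non-empty).
#' @return list: `statistic` (rank sum of `x`, midranks), `p_value`,
#'   `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  use_exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  p <- wt$p.value
  # fully tied pooled samples leave the normal approximation with zero
  # variance (NaN); there is no evidence either way
  if (!is.finite(p)) p <- 1
  ranks <- rank(c(x, y))
  list(statistic = sum(ranks[seq_along(x)]),
       p_value = p,
       exact = use_exact)
}

#' Screen subsystems for differential flux across states
#'
#' Per subsystem (>= 2 reactions), runs pairwise Wilcoxon rank-sum tests
#' between states using the per-reaction flux magnitudes within the
#' subsystem as replicate units (one model per state leaves no biological
#' replicates; this choice is recorded in the output). A subsystem is
#' flagged when any state pair has p < alpha; raw p-values are reported
#' without multiplicity correction by default (`p_adjust = "BH"` enables
#' Benjamini-Hochberg across pairs within each subsystem).
#'
#' @param flux_table reactions x states matrix.
#' @param model parent `metabolic_model`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list: `table` (data.frame: subsystem, n_reactions, min_p,
#'   flagged), `pairs` (long data.frame of all pairwise tests),
#'   `state_means` (subsystem x state mean |flux| matrix for display),
#'   `replicate_unit` (documentation string).
#' @export
subsystem_screen <- function(flux_table, model, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  states <- colnames(flux_table)
  stopifnot(length(states) >= 2L)
  subsys <- stats::setNames(model$reactions$subsystem, model$reactions$id)
  labels <- subsys[rownames(flux_table)]
  out_rows <- list(); pair_rows <- list()
  for (ss in sort(unique(labels))) {
    sel <- which(labels == ss)
    if (length(sel) < 2L) {
      warning("subsystem with < 2 reactions skipped: ", ss, call. = FALSE)
      next
    }
    sub <- abs(flux_table[sel, , drop = FALSE])
    pvals <- c()
    for (a in seq_along(states)) for (b in seq_along(states)) {
      if (a < b) {
        res <- wilcoxon_rank_sum(sub[, a], sub[, b])
        pair_rows[[length(pair_rows) + 1L]] <-
          data.frame(subsystem = ss, state_a = states[a], state_b = states[b],
                     statistic = res$statistic, p_value = res$p_value,
                     exact = res$exact, stringsAsFactors = FALSE)
        pvals <- c(pvals, res$p_value)
      }
    }
    if (p_adjust == "BH") pvals <- stats::p.adjust(pvals, method = "BH")
    out_rows[[length(out_rows) + 1L]] <-
      data.frame(subsystem = ss, n_reactions = length(sel),
                 min_p = min(pvals), flagged = any(pvals < alpha),
                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out_rows)
  pairs <- do.call(rbind, pair_rows)
  kept_ss <- tab$subsystem
  means <- t(sapply(kept_ss, function(ss) {
    colMeans(abs(flux_table[labels == ss, , drop = FALSE]))
  }))
  dimnames(means) <- list(kept_ss, states)
  list(table = tab, pairs = pairs, state_means = means,
       replicate_unit = "per-reaction |flux| within subsystem")
}

#' Hierarchical clustering of flux or expression rows
#'
#' Rows are z-scored internally (constant rows become zeros), distances
#' are 1 - Pearson correlation between rows, and the agglomerative tree
#' (average linkage by default) is cut into `k` clusters. Deterministic
#' for a given input order.
#'
#' @param mat items x conditions numeric matrix (>= k rows).
#' @param k number of clusters.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return object of class `cluster_assignment`: `cluster` (named integer
#'   vector), `k`, `linkage`, `distance`, `order` (dendrogram order of row
#'   names), `hclust` (the tree).
#' @export
hierarchical_cluster <- function(mat, k, linkage = "average") {
  if (k > nrow(mat)) stop("k exceeds the number of rows", call. = FALSE)
  z <- t(apply(mat, 1, zscore_safe))
  dimnames(z) <- dimnames(mat)
  cors <- suppressWarnings(stats::cor(t(z)))
  cors[!is.finite(cors)] <- 0  # constant (all-zero) rows: treat as uncorrelated
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = linkage)
  structure(list(cluster = stats::cutree(hc, k = k), k = k,
                 linkage = linkage, distance = "1 - Pearson",
                 order = rownames(mat)[hc$order], hclust = hc),
            class = "cluster_assignment")
}

#' Gene-rule frequency table per flux cluster
#'
#' Counts canonical gene rules among each cluster's reactions and reports
#' the most frequent rule per cluster with its count and fraction of the
#' cluster's reactions (no-GPR reactions are not counted toward any rule
#' but appear in the denominator and are reported separately). Ties are
#' broken lexicographically and flagged.
#'
#' @param clusters a `cluster_assignment` over reaction ids, or a named
#'   integer/character vector reaction -> cluster.
#' @param model the parent `metabolic_model`.
#' @return list: `table` (data.frame: cluster, rule, count, fraction),
#'   `most_frequent` (data.frame: cluster, rule, count, fraction, tied),
#'   `no_gpr` (data.frame: cluster, count).
#' @export
gene_rule_frequency <- function(clusters, model) {
  assign <- if (inherits(clusters, "cluster_assignment")) clusters$cluster else clusters
  unknown <- setdiff(names(assign), model$reactions$id)
  if (length(unknown)) stop("cluster reactions absent from model: ",
                            paste(utils::head(unknown, 5), collapse = ", "),
                            call. = FALSE)
  gpr_map <- stats::setNames(model$reactions$gpr, model$reactions$id)
  rows <- list(); top_rows <- list(); nogpr_rows <- list()
  for (cl in sort(unique(assign))) {
    rx <- names(assign)[assign == cl]
    total <- length(rx)
    rules_raw <- gpr_map[rx]
    ruled <- rx[nzchar(rules_raw)]
    nogpr_rows[[length(nogpr_rows) + 1L]] <-
      data.frame(cluster = cl, count = total - length(ruled))
    if (length(ruled) == 0L) next
    canon <- vapply(gpr_map[ruled], canonical_gpr, character(1))
    tab <- sort(table(canon), decreasing = TRUE)
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = cl, rule = names(tab), count = as.integer(tab),
                 fraction = as.integer(tab) / total, stringsAsFactors = FALSE)
    top_n <- max(tab)
    tied_rules <- sort(names(tab)[tab == top_n])
    top_rows[[length(top_rows) + 1L]] <-
      data.frame(cluster = cl, rule = tied_rules[1], count = top_n,
                 fraction = top_n / total, tied = length(tied_rules) > 1L,
                 stringsAsFactors = FALSE)
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(cluster = integer(0), rule = character(0),
                    count = integer(0), fraction = numeric(0)),
       most_frequent = if (length(top_rows)) do.call(rbind, top_rows) else
         data.frame(cluster = integer(0), rule = character(0),
                    count = integer(0), fraction = numeric(0), tied = logical(0)),
       no_gpr = do.call(rbind, nogpr_rows))
}

#' Classify transported species as imported or exported
#'
#' Each transport reaction, oriented by its flux sign, moves species
#' between compartments; a species is classified *import* when it ends up
#' in the designated interior compartment and *export* when it leaves it.
#' Species seen with exactly one direction within the set are kept; species
#' involved in both import and export are dropped (mixed direction), as
#' are movements not touching the interior compartment.
#'
#' @param reaction_ids transport reactions to map (error if any is not a
#'   derived transport reaction).
#' @param model the parent `metabolic_model`.
#' @param fluxes named numeric vector of signed fluxes for these
#'   reactions; zero-flux reactions are skipped.
#' @param interior compartment id designated as the cell interior
#'   (default `"c"`).
#' @return list: `kept` (data.frame: species, direction, n_reactions),
#'   `dropped_mixed` (character vector of mixed-direction species).
#' @export
transport_direction_map <- function(reaction_ids, model, fluxes,
                                    interior = "c") {
  rx <- model$reactions
  sel <- match(reaction_ids, rx$id)
  if (any(is.na(sel))) stop("unknown reactions: ",
                            paste(reaction_ids[is.na(sel)], collapse = ", "),
                            call. = FALSE)
  if (any(!rx$is_transport[sel])) {
    stop("not transport reactions: ",
         paste(reaction_ids[!rx$is_transport[sel]], collapse = ", "),
         call. = FALSE)
  }
  species <- metabolite_species(model)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  obs <- list()
  for (rid in reaction_ids) {
    v <- fluxes[[rid]]
    if (is.null(v) || is.na(v) || v == 0) next
    st <- model$stoichiometry[[rid]]
    st <- st * sign(v)  # orient by flux: positive = produced after orientation
    for (s in unique(species[names(st)])) {
      mets_s <- names(st)[species[names(st)] == s]
      from <- unique(comp[mets_s[st[mets_s] < 0]])
      to <- unique(comp[mets_s[st[mets_s] > 0]])
      if (length(from) == 0L || length(to) == 0L) next  # not moved, just consumed/produced
      dir <- if (interior %in% to && !(interior %in% from)) "import"
             else if (interior %in% from && !(interior %in% to)) "export"
             else NA_character_
      if (!is.na(dir)) {
        obs[[length(obs) + 1L]] <- data.frame(species = s, direction = dir,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(obs) == 0L) {
    return(list(kept = data.frame(species = character(0),
                                  direction = character(0),
                                  n_reactions = integer(0)),
                dropped_mixed = character(0)))
  }
  df <- do.call(rbind, obs)
  agg <- stats::aggregate(direction ~ species, df,
                          FUN = function(d) length(unique(d)))
  mixed <- agg$species[agg$direction > 1L]
  keep_df <- df[!(df$species %in% mixed), , drop = FALSE]
  if (nrow(keep_df) == 0L) {
    kept <- data.frame(species = character(0), direction = character(0),
                       n_reactions = integer(0))
  } else {
    keep_df$n_reactions <- 1
    kept <- stats::aggregate(n_reactions ~ species + direction, keep_df, FUN = sum)
    kept <- kept[order(kept$species), c("species", "direction", "n_reactions")]
    rownames(kept) <- NULL
  }
  list(kept = kept, dropped_mixed = sort(mixed))
}
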
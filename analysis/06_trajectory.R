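#!/usr/bin/env Rscript
# Stage 6 — PCA and MST pseudo-temporal trajectories.
#
# State-level PCA of (a) mean-TPM gene profiles and (b) predicted measurable
# fluxes; minimum spanning trees on Euclidean distances in the retained PC
# space (enough PCs for 90% variance, floor of two); depth-first orderings
# rooted at the healthy state with branch-point reporting.

suppressPackageStartupMessages(library(fluxgem))
outdir <- "results"
counts <- read_tsv_matrix(file.path(outdir, "counts.tsv"))
lengths <- read_tsv_map(file.path(outdir, "gene_lengths.tsv"), numeric = TRUE)
sample_state <- read_tsv_map(file.path(outdir, "sample_state.tsv"))
measurable <- read_tsv_matrix(file.path(outdir, "measurable_fluxes.tsv"))
tpm <- tpm_normalize(counts, lengths)
profiles <- aggregate_states(tpm, sample_state, method = "mean")

run_traj <- function(mat, scale., label) {
  pca <- pca_states(mat, scale. = scale.)
  cum <- cumsum(pca$variance_explained)
  n_pc <- max(2L, which(cum >= 0.9)[1])
  n_pc <- min(n_pc, length(pca$variance_explained))
  mst <- minimum_spanning_tree(pca$coordinates[, seq_len(n_pc), drop = FALSE])
  tr <- extract_trajectory(mst, root = "healthy")
  cat(sprintf("[%s] PC1 %.1f%%, PC2 %.1f%% of variance; %d PCs for MST\n",
              label, 100 * pca$variance_explained[1],
              100 * pca$variance_explained[2], n_pc))
  cat(sprintf("[%s] ordering from healthy: %s\n", label,
              paste(tr$ordering, collapse = " -> ")))
  cat(sprintf("[%s] branch points: %s\n", label,
              if (length(tr$branch_points)) paste(tr$branch_points, collapse = ", ")
              else "none"))
  list(pca = pca, mst = mst, trajectory = tr, n_pc = n_pc)
}

gene_mat <- log2(t(sapply(names(profiles), function(s) profiles[[s]]$gene_values)) + 1)
tg <- run_traj(gene_mat, scale. = FALSE, "genes")
tf <- run_traj(t(measurable), scale. = FALSE, "fluxes")

write_tsv_matrix(tf$pca$coordinates, file.path(outdir, "flux_pc_coordinates.tsv"),
                 "state")
utils::write.table(tf$mst, file.path(outdir, "flux_mst_edges.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(genes = tg$trajectory, fluxes = tf$trajectory),
  file.path(outdir, "trajectories.json"), auto_unbox = TRUE, digits = NA)
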
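#!/usr/bin/env Rscript
# Stage 5 — flux statistics.
#
# Subsystem |flux| sums, the pairwise Wilcoxon rank-sum screen across states
# (per-reaction fluxes as replicate units, raw p < 0.05), hierarchical
# clustering of measurable fluxes into two clusters, and the transport-flux
# analysis: four clusters, gene-rule frequency tables with the dominant rule
# per cluster, and the import/export map of unambiguously directed species.

suppressPackageStartupMessages(library(fluxgem))
outdir <- "results"
model <- read_model(file.path(outdir, "model.json"))
measurable <- read_tsv_matrix(file.path(outdir, "measurable_fluxes.tsv"))

sums <- subsystem_flux_sums(measurable, model)
write_tsv_matrix(sums$sums, file.path(outdir, "subsystem_flux_sums.tsv"),
                 "subsystem")

screen <- suppressWarnings(subsystem_screen(measurable, model, alpha = 0.05))
utils::write.table(screen$table, file.path(outdir, "subsystem_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv_matrix(screen$state_means, file.path(outdir, "subsystem_state_means.tsv"),
                 "subsystem")
cat("significant subsystems (any pairwise p < 0.05):",
    paste(screen$table$subsystem[screen$table$flagged], collapse = ", "), "\n")

cl2 <- hierarchical_cluster(measurable, k = 2)
utils::write.table(
  data.frame(reaction = names(cl2$cluster), cluster = unname(cl2$cluster)),
  file.path(outdir, "flux_clusters.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("flux clusters (k=2): sizes %s\n",
            paste(table(cl2$cluster), collapse = " / ")))

is_tr <- stats::setNames(model$reactions$is_transport, model$reactions$id)
transport_rx <- rownames(measurable)[is_tr[rownames(measurable)]]
if (length(transport_rx) >= 4) {
  cl4 <- hierarchical_cluster(measurable[transport_rx, , drop = FALSE], k = 4)
  freq <- gene_rule_frequency(cl4, model)
  utils::write.table(freq$table, file.path(outdir, "transport_rule_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("dominant transport gene rules per cluster:\n")
  print(freq$most_frequent, row.names = FALSE)
  for (cl in sort(unique(cl4$cluster))) {
    rx <- names(cl4$cluster)[cl4$cluster == cl]
    dir_map <- transport_direction_map(
      rx, model, fluxes = rowMeans(measurable[rx, , drop = FALSE]),
      interior = "c")
    if (nrow(dir_map$kept)) {
      utils::write.table(dir_map$kept,
                         file.path(outdir, sprintf("transport_direction_c%d.tsv", cl)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
}
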
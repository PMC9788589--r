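#!/usr/bin/env Rscript
# Stage 3 — structural comparison of the extracted models.
#
# Presence/absence matrix over the union reaction set, pairwise Hamming
# similarity, rank ordering of model sizes (reactions, metabolites, genes,
# unique canonical gene rules), the >10% subsystem coverage screen, and the
# gene-rule drill-down for the flagged subsystems with z-scored expression.

suppressPackageStartupMessages(library(fluxgem))
outdir <- "results"
model <- read_model(file.path(outdir, "model.json"))
counts <- read_tsv_matrix(file.path(outdir, "counts.tsv"))
lengths <- read_tsv_map(file.path(outdir, "gene_lengths.tsv"), numeric = TRUE)
sample_state <- read_tsv_map(file.path(outdir, "sample_state.tsv"))
tpm <- tpm_normalize(counts, lengths)
profiles <- aggregate_states(tpm, sample_state, method = "max")

contexts <- lapply(names(profiles), function(s) {
  tab <- utils::read.delim(file.path(outdir, sprintf("context_%s.tsv", s)))
  ctx <- structure(list(parent_id = model$id, state = s,
                        kept_reactions = tab$reaction,
                        provenance = stats::setNames(tab$provenance,
                                                     tab$reaction),
                        threshold = 1),
                   class = "context_model")
  ctx
})

pres <- presence_matrix(contexts)
sim <- hamming_similarity(pres)
write_tsv_matrix(sim, file.path(outdir, "hamming_similarity.tsv"), "model")
cat(sprintf("Hamming similarity over %d union reactions: min %.3f, max off-diagonal %.3f\n",
            nrow(pres), min(sim), max(sim[upper.tri(sim)])))

ranks <- rank_models(contexts, model)
utils::write.table(ranks, file.path(outdir, "model_ranks.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("largest model by reactions:", ranks$model[which.min(ranks$rank_reactions)],
    "\n")

ds <- differential_subsystems(contexts, model, pct = 10)
utils::write.table(ds, file.path(outdir, "differential_subsystems.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
flagged <- ds$subsystem[ds$flagged]
cat("subsystems with >10% pairwise coverage difference:",
    if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")

if (length(flagged)) {
  dd <- gene_rule_drilldown(contexts, model, flagged, state_profiles = profiles)
  cat(sprintf("drill-down: %d differing reactions, %d with rules, %d unique rules\n",
              dd$n_differing, dd$n_with_rules, dd$n_unique_rules))
  utils::write.table(dd$rules, file.path(outdir, "drilldown_rules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dd$gene_zscores)) {
    write_tsv_matrix(dd$gene_zscores, file.path(outdir, "drilldown_gene_z.tsv"),
                     "gene")
  }
}
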
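#!/usr/bin/env Rscript
# Stage 2 — context-specific model extraction.
#
# TPM-normalizes the counts, aggregates per state (max-TPM, the threshold
# rule's convention), scores every reaction through its GPR rule, extracts one
# context model per state with the strict 1-TPM threshold, and gap-fills any
# state that lost a viability task. Writes per-state context tables with
# provenance (expression_supported / no_gpr_retained / task_rescued).

suppressPackageStartupMessages(library(fluxgem))
outdir <- "results"
model <- read_model(file.path(outdir, "model.json"))
tasks <- read_tasks(file.path(outdir, "tasks.json"))
counts <- read_tsv_matrix(file.path(outdir, "counts.tsv"))
lengths <- read_tsv_map(file.path(outdir, "gene_lengths.tsv"), numeric = TRUE)
sample_state <- read_tsv_map(file.path(outdir, "sample_state.tsv"))

tpm <- tpm_normalize(counts, lengths)
profiles <- aggregate_states(tpm, sample_state, method = "max")

for (s in names(profiles)) {
  scores <- score_reactions(model, profiles[[s]])
  ctx <- threshold_extract(model, scores, threshold = 1)
  ctx <- gap_fill(ctx, model, tasks)
  tab <- table(ctx$provenance)
  cat(sprintf("%-15s kept %3d reactions (%s)\n", s,
              length(ctx$kept_reactions),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  utils::write.table(
    data.frame(reaction = ctx$kept_reactions,
               provenance = unname(ctx$provenance[ctx$kept_reactions])),
    file.path(outdir, sprintf("context_%s.tsv", s)), sep = "\t",
    quote = FALSE, row.names = FALSE)
}
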
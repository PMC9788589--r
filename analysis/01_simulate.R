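#!/usr/bin/env Rscript
# Stage 1 — synthetic eight-state liver study.
#
# Generates the toy genome-scale model (three compartments, linear
# import-convert-export pathways, dedicated GPR rules), the viability task
# list, ground-truth state fluxes with the planted sequentially dysregulated
# GSH-like chain (explant AH > severe AH > non-severe AH > early ASH) and the
# NALD-perturbed branch, and the noisy RNA-seq counts. Everything downstream
# reads from results/.

suppressPackageStartupMessages(library(fluxgem))
seed <- 1L
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
ds <- simulate_dataset(cfg)

write_model(ds$model, file.path(outdir, "model.json"))
write_tasks(ds$tasks, file.path(outdir, "tasks.json"))
write_tsv_matrix(ds$truth$flux, file.path(outdir, "ground_truth_flux.tsv"),
                 "reaction")
write_tsv_matrix(ds$expression$counts, file.path(outdir, "counts.tsv"), "gene")
utils::write.table(
  data.frame(gene = names(ds$expression$lengths),
             length = unname(ds$expression$lengths)),
  file.path(outdir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(sample = names(ds$expression$sample_state),
             state = unname(ds$expression$sample_state)),
  file.path(outdir, "sample_state.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf("model: %d reactions, %d metabolites, %d genes, %d pathways\n",
            nrow(ds$model$reactions), nrow(ds$model$metabolites),
            length(ds$model$genes), length(unique(ds$pathways$pathway))))
cat(sprintf("expression: %d genes x %d samples across %d states\n",
            nrow(ds$expression$counts), ncol(ds$expression$counts),
            length(cfg$states)))
cat("planted ALD ordering:", paste(ds$truth$planted$ald_path, collapse = " -> "),
    "\n")
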
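#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one declarative
#' list: the simulation config (or paths to user-supplied inputs), the
#' extraction threshold (1 TPM, strict), the aggregation methods (max-TPM
#' for the threshold rule, mean-TPM for flux scoring), the measurable-flux
#' threshold (0.1 mmol/gDW/h), the screen alpha (0.05, raw), cluster
#' counts (2 for measurable fluxes, 4 for transport fluxes), the interior
#' compartment for import/export calls, and the PC-variance fraction
#' retained for MST distances.
#'
#' @param seed integer seed driving the simulation and any stochastic
#'   stage.
#' @param ... overrides for any config entry.
#' @return named list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulation = simulation_config(seed = seed),
    threshold = 1.0,
    extract_aggregation = "max",
    flux_aggregation = "mean",
    measurable_threshold = 0.1,
    alpha = 0.05,
    k_fluxes = 2L,
    k_transport = 4L,
    interior_compartment = "c",
    pc_variance = 0.9,
    pc_min = 2L,
    trajectory_root = "healthy")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: simulate -> TPM/aggregate -> extract context models (per
#' state) + task gap-fill -> structural comparison -> SPOT + E-Flux2 flux
#' prediction (per state) -> measurable-flux filter -> subsystem flux
#' statistics and clustering -> transport gene-rule analysis -> PCA/MST
#' trajectories. Pure function of the config (all randomness seeded);
#' rerunning with the same config writes byte-identical tables.
#'
#' @param config from [pipeline_config()].
#' @param outdir optional directory; when given, every stage's tables are
#'   written there as TSV/JSON along with a run manifest.
#' @return list with all stage outputs (see the pipeline vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  sim <- simulate_dataset(config$simulation)
  model <- sim$model
  states <- config$simulation$states

  tpm <- tpm_normalize(sim$expression$counts, sim$expression$lengths)
  prof_extract <- aggregate_states(tpm, sim$expression$sample_state,
                                   method = config$extract_aggregation)
  prof_flux <- aggregate_states(tpm, sim$expression$sample_state,
                                method = config$flux_aggregation)

  contexts <- list()
  for (s in states) {
    scores <- score_reactions(model, prof_extract[[s]])
    ctx <- threshold_extract(model, scores, threshold = config$threshold)
    contexts[[s]] <- gap_fill(ctx, model, sim$tasks)
  }

  pres <- presence_matrix(contexts)
  similarity <- hamming_similarity(pres)
  ranks <- rank_models(contexts, model)
  diff_ss <- differential_subsystems(contexts, model)
  drill <- gene_rule_drilldown(contexts, model,
                               subsystems = diff_ss$subsystem[diff_ss$flagged],
                               state_profiles = prof_extract)

  flux_results <- list()
  for (s in states) {
    scores_s <- score_reactions(model, prof_flux[[s]])
    spot <- spot_objective(contexts[[s]], scores_s, parent = model)
    bounds <- eflux2_bounds(contexts[[s]], scores_s, parent = model)
    flux_results[[s]] <- eflux2_solve(contexts[[s]], spot$f_prime,
                                      bounds = bounds, parent = model,
                                      state = s)
  }
  measurable <- measurable_fluxes(flux_results,
                                  threshold = config$measurable_threshold)

  ss_sums <- subsystem_flux_sums(measurable, model)
  screen <- subsystem_screen(measurable, model, alpha = config$alpha)
  flux_clusters <- hierarchical_cluster(measurable,
                                        k = min(config$k_fluxes, nrow(measurable)))

  is_transport <- stats::setNames(model$reactions$is_transport,
                                  model$reactions$id)
  transport_rx <- rownames(measurable)[is_transport[rownames(measurable)]]
  transport <- NULL
  if (length(transport_rx) >= config$k_transport) {
    tr_clusters <- hierarchical_cluster(measurable[transport_rx, , drop = FALSE],
                                        k = config$k_transport)
    freq <- gene_rule_frequency(tr_clusters, model)
    direction <- lapply(sort(unique(tr_clusters$cluster)), function(cl) {
      rx <- names(tr_clusters$cluster)[tr_clusters$cluster == cl]
      transport_direction_map(rx, model,
                              fluxes = rowMeans(measurable[rx, , drop = FALSE]),
                              interior = config$interior_compartment)
    })
    transport <- list(clusters = tr_clusters, rule_frequency = freq,
                      direction_maps = direction)
  }

  # trajectories: gene-level (log2 mean TPM per state; log stabilizes
  # variance so flat background genes do not dominate) and flux-level
  gene_mat <- log2(t(sapply(states, function(s) prof_flux[[s]]$gene_values)) + 1)
  traj_genes <- trajectory_from_matrix(gene_mat, config, scale. = FALSE)
  flux_mat <- t(measurable)
  traj_flux <- trajectory_from_matrix(flux_mat, config, scale. = FALSE)

  out <- list(config = config, sim = sim, tpm = tpm,
              profiles = list(extract = prof_extract, flux = prof_flux),
              contexts = contexts,
              comparison = list(presence = pres, similarity = similarity,
                                ranks = ranks,
                                differential_subsystems = diff_ss,
                                drilldown = drill),
              flux_results = flux_results, measurable = measurable,
              statistics = list(subsystem_sums = ss_sums, screen = screen,
                                flux_clusters = flux_clusters,
                                transport = transport),
              trajectories = list(genes = traj_genes, fluxes = traj_flux))
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# PCA -> retain PCs covering config$pc_variance -> Euclidean MST -> DFS
# ordering from the configured root
trajectory_from_matrix <- function(mat, config, scale. = FALSE) {
  pca <- pca_states(mat, scale. = scale.)
  cum <- cumsum(pca$variance_explained)
  n_pc <- which(cum >= config$pc_variance)[1]
  if (is.na(n_pc)) n_pc <- length(pca$variance_explained)
  # a floor of two components keeps branch geometry from collapsing onto a
  # single dominant axis
  n_pc <- min(max(n_pc, config$pc_min), length(pca$variance_explained))
  coords <- pca$coordinates[, seq_len(n_pc), drop = FALSE]
  mst <- minimum_spanning_tree(coords)
  traj <- extract_trajectory(mst, root = config$trajectory_root)
  list(pca = pca, n_pc = n_pc, mst = mst, trajectory = traj)
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_model(out$sim$model, p("model.json"))
  write_tasks(out$sim$tasks, p("tasks.json"))
  write_tsv_matrix(out$sim$truth$flux, p("ground_truth_flux.tsv"), "reaction")
  for (s in names(out$contexts)) {
    ctx <- out$contexts[[s]]
    utils::write.table(
      data.frame(reaction = ctx$kept_reactions,
                 provenance = unname(ctx$provenance[ctx$kept_reactions])),
      p(sprintf("context_%s.tsv", s)), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  write_tsv_matrix(out$comparison$presence + 0, p("presence_matrix.tsv"), "reaction")
  write_tsv_matrix(out$comparison$similarity, p("hamming_similarity.tsv"), "model")
  utils::write.table(out$comparison$ranks, p("model_ranks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$comparison$differential_subsystems,
                     p("differential_subsystems.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(out$measurable, p("measurable_fluxes.tsv"), "reaction")
  write_tsv_matrix(out$statistics$subsystem_sums$sums, p("subsystem_flux_sums.tsv"),
                   "subsystem")
  utils::write.table(out$statistics$screen$table, p("subsystem_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(reaction = names(out$statistics$flux_clusters$cluster),
               cluster = unname(out$statistics$flux_clusters$cluster)),
    p("flux_clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(root = out$trajectories$fluxes$trajectory$root,
         ordering = out$trajectories$fluxes$trajectory$ordering,
         branch_points = out$trajectories$fluxes$trajectory$branch_points,
         mst = out$trajectories$fluxes$mst),
    p("trajectory_fluxes.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fluxgem")),
    seed = out$config$seed,
    config_hash = config_hash(out$config),
    tolerances = fluxgem_tol(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

# stable hash of the config (timestamp-free): md5 of its canonical JSON
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
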
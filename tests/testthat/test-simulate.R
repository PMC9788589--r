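test_that("the generator is deterministic and produces valid models", {
  cfg <- simulation_config(seed = 1)
  sim1 <- generate_model(cfg)
  sim2 <- generate_model(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_model(sim1$model, f1); write_model(sim2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gte(nrow(sim1$model$reactions), cfg$n_reactions)
  expect_silent(validate_model(sim1$model))
  # every generated task is feasible on the full model
  for (task in sim1$tasks) {
    expect_true(check_task(sim1$model, task)$feasible)
  }
})

test_that("GPR rule types appear in roughly the configured proportions", {
  cfg <- simulation_config(seed = 2, n_reactions = 120L)
  sim <- generate_model(cfg)
  rules <- sim$model$reactions$gpr[nzchar(sim$model$reactions$gpr)]
  kind <- ifelse(grepl(" AND ", rules), "and",
                 ifelse(grepl(" OR ", rules), "or", "single"))
  freq <- table(factor(kind, levels = c("single", "and", "or"))) / length(kind)
  # binomial sampling bands around the configured proportions
  expect_lt(abs(freq[["single"]] - 0.5), 0.15)
  expect_lt(abs(freq[["and"]] - 0.25), 0.15)
  expect_lt(abs(freq[["or"]] - 0.25), 0.15)
})

test_that("ground-truth fluxes satisfy steady state and planted ordering", {
  cfg <- simulation_config(seed = 3)
  sim <- generate_model(cfg)
  truth <- generate_state_fluxes(sim, cfg)
  S <- stoich_matrix(sim$model)
  expect_lte(max(abs(S %*% truth$flux)), 1e-8)
  # planted chain flux strictly ordered across the ALD states
  chain <- truth$planted$chain_reactions
  lvl <- colMeans(abs(truth$flux[chain, , drop = FALSE]))
  expect_lt(lvl["healthy"], lvl["early_ASH"])
  expect_lt(lvl["early_ASH"], lvl["nonsevere_AH"])
  expect_lt(lvl["nonsevere_AH"], lvl["severe_AH"])
  expect_lt(lvl["severe_AH"], lvl["explant_AH"])
  # dormant pathways carry no flux anywhere
  expect_equal(max(abs(truth$flux[truth$planted$dormant_reactions, ])), 0)
  # all multipliers 1: every state shares the base flux
  cfg_flat <- cfg
  cfg_flat$ald_multipliers[] <- c(1, 1, 1, 1) + c(0, 1e-9, 2e-9, 3e-9)
  cfg_flat$nald_multipliers[] <- 1
  cfg_flat$filler_jitter_sd <- 0
  sim_f <- generate_model(cfg_flat)
  # force the ald-only and dormant roles inactive for this check
  sim_f$pathways$role_class[sim_f$pathways$role_class %in%
                              c("ald_only", "dormant")] <- "filler"
  truth_f <- generate_state_fluxes(sim_f, cfg_flat)
  spread <- apply(truth_f$flux, 1, function(r) diff(range(r)))
  expect_lte(max(spread), 1e-6)
})

test_that("noiseless expression reproduces designed TPM and activity scores", {
  cfg <- simulation_config(seed = 4, dispersion = 0)
  sim <- generate_model(cfg)
  truth <- generate_state_fluxes(sim, cfg)
  em <- generate_expression(sim, truth, cfg)
  designed <- attr(em, "designed_tpm")
  tpm <- tpm_normalize(em$counts, em$lengths)
  # each sample's TPM equals its state's designed mean
  for (smp in colnames(tpm)[c(1, 20, 50)]) {
    st <- em$sample_state[[smp]]
    expect_equal(unname(tpm[, smp]), unname(designed[, st]), tolerance = 1e-6)
  }
  # noiseless GPR scores exceed the 1-TPM threshold exactly for active
  # reactions (per state)
  for (st in c("healthy", "explant_AH")) {
    prof <- structure(list(state = st, gene_values = designed[, st]),
                      class = "state_profile")
    sc <- score_reactions(sim$model, prof)
    active <- intersect(names(sc$scores), truth$active[[st]])
    inactive <- setdiff(names(sc$scores), truth$active[[st]])
    expect_true(all(sc$scores[active] > 1))
    expect_true(all(sc$scores[inactive] < 1))
  }
  # same seed, same counts
  em2 <- generate_expression(sim, truth, cfg)
  expect_identical(em$counts, em2$counts)
})

test_that("generator outputs re-validate through the package containers", {
  cfg <- simulation_config(seed = 6)
  ds <- simulate_dataset(cfg)
  expect_s3_class(ds$model, "metabolic_model")
  expect_s3_class(ds$expression, "expression_matrix")
  expect_equal(sum(cfg$samples_per_state), ncol(ds$expression$counts))
  # per-state sample sizes mirror the cohort design
  expect_equal(
    as.integer(table(ds$expression$sample_state)[names(cfg$samples_per_state)]),
    unname(cfg$samples_per_state))
  # round-trip through the JSON dialect
  f <- tempfile(fileext = ".json")
  write_model(ds$model, f)
  expect_silent(m2 <- read_model(f))
  expect_equal(m2$reactions$id, ds$model$reactions$id)
})
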
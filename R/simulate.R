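#' Configuration for the synthetic liver-state study generator
#'
#' Defaults emulate the eight-state cohort design: four ALD states
#' (explant AH > severe AH > non-severe AH > early ASH in severity), a
#' healthy control, and three NALD states (compensated cirrhosis, HCV,
#' NASH), with the study's per-state sample sizes. The toy network is
#' assembled from linear import-convert-export pathways across three
#' compartments; pathway 1 is the planted "GSH-like" chain whose flux is
#' sequentially dysregulated across the ALD states (monotone effect
#' multipliers), pathway 2 is the NALD-perturbed branch, pathway 3 is
#' active only in ALD states, and the last two pathways are dormant
#' everywhere (their GPR scores stay below the extraction threshold).
#'
#' @param seed integer; fixes all downstream randomness.
#' @param samples_per_state named integer vector (state -> n samples).
#' @param n_reactions target network size (default 60).
#' @param gpr_mix proportions of single-gene / AND-pair / OR-pair rules
#'   for internal and transport reactions.
#' @param ald_multipliers monotone effect multipliers on the planted chain
#'   for the ALD states (must increase with severity).
#' @param nald_multipliers effect multipliers on the branch chain for the
#'   NALD states.
#' @param dispersion negative-binomial dispersion of the count noise
#'   (`0` = noiseless expectation).
#' @param tpm_per_flux designed TPM per unit of ground-truth flux for the
#'   genes of an active reaction.
#' @param inactive_tpm designed TPM for genes of inactive reactions
#'   (below the 1-TPM threshold).
#' @param n_background_genes non-model genes absorbing the rest of the
#'   library (so model-gene TPM sits on an absolute scale).
#' @param filler_jitter_sd multiplicative per-state jitter (s.d., log
#'   scale approximated as gaussian) on non-planted pathway fluxes.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    samples_per_state = c(explant_AH = 10L, severe_AH = 18L, nonsevere_AH = 11L,
                          early_ASH = 12L, healthy = 10L, comp_cirrhosis = 9L,
                          HCV = 10L, NASH = 9L),
    n_reactions = 60L,
    gpr_mix = c(single = 0.5, and = 0.25, or = 0.25),
    ald_multipliers = c(early_ASH = 2, nonsevere_AH = 4, severe_AH = 8,
                        explant_AH = 16),
    nald_multipliers = c(NASH = 2, HCV = 4, comp_cirrhosis = 8),
    dispersion = 0.1,
    tpm_per_flux = 10,
    inactive_tpm = 0.2,
    n_background_genes = 300L,
    filler_jitter_sd = 0.03) {
  stopifnot(all(diff(unname(ald_multipliers)) > 0))
  cfg <- list(seed = as.integer(seed),
              states = names(samples_per_state),
              samples_per_state = samples_per_state,
              n_reactions = as.integer(n_reactions),
              gpr_mix = gpr_mix / sum(gpr_mix),
              ald_multipliers = ald_multipliers,
              nald_multipliers = nald_multipliers,
              dispersion = dispersion,
              tpm_per_flux = tpm_per_flux,
              inactive_tpm = inactive_tpm,
              n_background_genes = as.integer(n_background_genes),
              filler_jitter_sd = filler_jitter_sd,
              ald_order = c("healthy", "early_ASH", "nonsevere_AH",
                            "severe_AH", "explant_AH"),
              nald_order = c("healthy", "NASH", "HCV", "comp_cirrhosis"))
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a toy metabolic model and its task list
#'
#' The network is a set of linear pathways, each: exchange source ->
#' import transport -> one or two internal conversions (every third
#' pathway routed through the organelle compartment, adding two more
#' transports) -> export transport -> exchange sink. Every internal and
#' transport reaction gets a dedicated GPR rule (single gene, AND pair =
#' enzyme complex, or OR pair = isozymes, drawn per `gpr_mix`); exchange
#' reactions have none. One viability task per planted chain (produce the
#' product from the precursor) is returned alongside. Deterministic given
#' the config seed.
#'
#' @param config a `simulation_config`.
#' @return list: `model` (validated `metabolic_model`), `tasks`,
#'   `pathways` (data.frame reaction -> pathway, role), `capacities`
#'   (named per-pathway base flux levels).
#' @export
generate_model <- function(config = simulation_config()) {
  set.seed(config$seed)
  comps <- data.frame(id = c("e", "c", "m"),
                      name = c("extracellular", "cytosol", "organelle"),
                      stringsAsFactors = FALSE)
  subsys_palette <- c("Glycolysis", "TCA cycle", "Amino acid metabolism",
                      "Fatty acid oxidation", "Nucleotide metabolism",
                      "Pentose phosphate pathway")
  mets <- list(); rxns <- list(); stoich <- list(); genes <- character(0)
  pathway_rows <- list()

  add_met <- function(species, comp) {
    id <- paste0(species, "_", comp)
    mets[[id]] <<- data.frame(id = id, name = species, compartment = comp,
                              stringsAsFactors = FALSE)
    id
  }
  gene_counter <- 0L
  draw_gpr <- function() {
    kind <- sample(names(config$gpr_mix), 1L, prob = config$gpr_mix)
    ng <- if (kind == "single") 1L else 2L
    ids <- sprintf("G%04d", gene_counter + seq_len(ng))
    gene_counter <<- gene_counter + ng
    genes <<- c(genes, ids)
    if (kind == "single") ids
    else paste(ids, collapse = paste0(" ", toupper(kind), " "))
  }
  add_rxn <- function(id, st, lb, ub, subsystem, gpr, pathway, role) {
    rxns[[id]] <<- data.frame(id = id, name = id, lower_bound = lb,
                              upper_bound = ub, subsystem = subsystem,
                              gpr = gpr, stringsAsFactors = FALSE)
    stoich[[id]] <<- st
    pathway_rows[[id]] <<- data.frame(reaction = id, pathway = pathway,
                                      role = role, stringsAsFactors = FALSE)
  }

  build_pathway <- function(k, species, subsystem, via_organelle = FALSE,
                            two_steps = FALSE, reversible_conv = FALSE) {
    s <- species[1]; p <- species[2]
    se <- add_met(s, "e"); sc <- add_met(s, "c")
    pe <- add_met(p, "e"); pc <- add_met(p, "c")
    pid <- paste0("P", k)
    add_rxn(paste0("EX_", s), stats::setNames(1, se), 0, 1000,
            "Exchange/demand reactions", "", pid, "exchange_in")
    add_rxn(paste0("TR_", s), stats::setNames(c(-1, 1), c(se, sc)), 0, 1000,
            "Transport reactions", draw_gpr(), pid, "import")
    if (via_organelle) {
      sm <- add_met(s, "m"); pm <- add_met(p, "m")
      add_rxn(paste0("TRM_", s), stats::setNames(c(-1, 1), c(sc, sm)), 0, 1000,
              "Transport reactions", draw_gpr(), pid, "organelle_import")
      add_rxn(paste0("CONV_", s), stats::setNames(c(-1, 1), c(sm, pm)),
              if (reversible_conv) -1000 else 0, 1000,
              subsystem, draw_gpr(), pid, "conversion")
      add_rxn(paste0("TRM_", p), stats::setNames(c(-1, 1), c(pm, pc)), 0, 1000,
              "Transport reactions", draw_gpr(), pid, "organelle_export")
    } else if (two_steps) {
      ic <- add_met(paste0(s, "i"), "c")
      add_rxn(paste0("CONV1_", s), stats::setNames(c(-1, 1), c(sc, ic)), 0, 1000,
              subsystem, draw_gpr(), pid, "conversion")
      add_rxn(paste0("CONV2_", s), stats::setNames(c(-1, 1), c(ic, pc)),
              if (reversible_conv) -1000 else 0, 1000,
              subsystem, draw_gpr(), pid, "conversion")
    } else {
      add_rxn(paste0("CONV_", s), stats::setNames(c(-1, 1), c(sc, pc)),
              if (reversible_conv) -1000 else 0, 1000,
              subsystem, draw_gpr(), pid, "conversion")
    }
    add_rxn(paste0("TR_", p), stats::setNames(c(-1, 1), c(pc, pe)), 0, 1000,
            "Transport reactions", draw_gpr(), pid, "export")
    add_rxn(paste0("EX_", p), stats::setNames(-1, pe), 0, 1000,
            "Exchange/demand reactions", "", pid, "exchange_out")
  }

  # pathway 1: planted GSH-like ALD chain (two cytosolic synthesis steps)
  build_pathway(1, c("gsul", "gshx"), "Glutathione metabolism", two_steps = TRUE)
  # pathway 2: NALD-perturbed branch chain
  build_pathway(2, c("arach", "eicos"), "Eicosanoid metabolism", two_steps = TRUE)
  # filler pathways until the target size; every 3rd via the organelle,
  # every 4th with a reversible conversion
  k <- 2L
  while (sum(vapply(rxns, nrow, integer(1))) < config$n_reactions) {
    k <- k + 1L
    build_pathway(k, c(sprintf("met%02da", k), sprintf("met%02db", k)),
                  subsys_palette[((k - 3L) %% length(subsys_palette)) + 1L],
                  via_organelle = (k %% 3L == 0L),
                  reversible_conv = (k %% 4L == 0L))
  }
  n_pathways <- k
  pathways <- do.call(rbind, pathway_rows)
  rownames(pathways) <- NULL
  # roles of the planted pathways
  pathways$role_class <- "filler"
  pathways$role_class[pathways$pathway == "P1"] <- "ald_chain"
  pathways$role_class[pathways$pathway == "P2"] <- "nald_chain"
  pathways$role_class[pathways$pathway == "P3"] <- "ald_only"
  dormant <- paste0("P", c(n_pathways - 1L, n_pathways))
  pathways$role_class[pathways$pathway %in% dormant] <- "dormant"

  capacities <- stats::setNames(round(stats::runif(n_pathways, 2, 5), 3),
                                paste0("P", seq_len(n_pathways)))
  model <- metabolic_model(
    id = sprintf("toyGEM_seed%d", config$seed),
    compartments = comps,
    metabolites = do.call(rbind, mets),
    reactions = do.call(rbind, rxns),
    stoichiometry = stoich,
    genes = genes)
  tasks <- list(
    metabolic_task("T_gsh", inputs = list(list(metabolite = "gsul_e", max = 10)),
                   outputs = list(list(metabolite = "gshx_e", min = 0.1)),
                   description = "synthesize and export the GSH-like product"),
    metabolic_task("T_eicos", inputs = list(list(metabolite = "arach_e", max = 10)),
                   outputs = list(list(metabolite = "eicos_e", min = 0.1)),
                   description = "synthesize and export the branch product"))
  list(model = model, tasks = tasks, pathways = pathways,
       capacities = capacities)
}

# per-pathway effect multiplier for each state
state_multipliers <- function(config, pathways) {
  pw_ids <- unique(pathways$pathway)
  role_of <- stats::setNames(pathways$role_class[!duplicated(pathways$pathway)],
                             pw_ids)
  mult <- matrix(1, nrow = length(pw_ids), ncol = length(config$states),
                 dimnames = list(pw_ids, config$states))
  ald_states <- names(config$ald_multipliers)
  for (pw in pw_ids) {
    if (role_of[pw] == "ald_chain") {
      mult[pw, ald_states] <- config$ald_multipliers
    } else if (role_of[pw] == "nald_chain") {
      mult[pw, names(config$nald_multipliers)] <- config$nald_multipliers
    } else if (role_of[pw] == "ald_only") {
      mult[pw, ] <- 0
      mult[pw, ald_states] <- 1
    } else if (role_of[pw] == "dormant") {
      mult[pw, ] <- 0
    }
  }
  mult
}

#' Generate ground-truth state fluxes with planted dysregulation
#'
#' For each state: a base feasible flux is sampled by maximizing a random
#' positive objective over the network with per-pathway capacity caps on
#' the exchange inputs (each pathway saturates its cap), the planted
#' chains are rescaled by the state's effect multipliers (monotone across
#' the ALD states), non-planted pathways receive small multiplicative
#' jitter, and the result is re-projected onto the steady-state polytope
#' (l2 projection under the model's bounds).
#'
#' @param sim output of [generate_model()].
#' @param config the same `simulation_config`.
#' @return list of class `ground_truth`: `flux` (reactions x states),
#'   `active` (list per state of reaction ids with |v| > 1e-6),
#'   `multipliers`, `planted` (trajectory orderings and reaction sets).
#' @export
generate_state_fluxes <- function(sim, config = simulation_config()) {
  set.seed(config$seed + 1L)
  model <- sim$model
  pathways <- sim$pathways
  S <- stoich_matrix(model)
  rx_ids <- model$reactions$id
  pw_of <- stats::setNames(pathways$pathway, pathways$reaction)[rx_ids]
  mult <- state_multipliers(config, pathways)

  # base flux: random-objective LP with exchange inputs capped at the
  # pathway capacities
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  ub_capped <- ub
  is_ex_in <- pathways$role[match(rx_ids, pathways$reaction)] == "exchange_in"
  ub_capped[is_ex_in] <- sim$capacities[pw_of[is_ex_in]]
  w <- stats::runif(length(rx_ids), 0.5, 1)
  base <- solve_fba_lp(S, w, pmax(lb, 0), ub_capped)
  if (base$status != "optimal") stop("base flux sampling failed", call. = FALSE)
  v_base <- stats::setNames(base$v, rx_ids)

  flux <- matrix(0, nrow = length(rx_ids), ncol = length(config$states),
                 dimnames = list(rx_ids, config$states))
  for (s in config$states) {
    scale_rxn <- mult[pw_of, s]
    jitter <- stats::setNames(rep(1, length(rx_ids)), rx_ids)
    filler_pw <- rownames(mult)[apply(mult == 1, 1, all)]
    for (pw in filler_pw) {
      jitter[pw_of == pw] <- max(0, 1 + stats::rnorm(1, 0, config$filler_jitter_sd))
    }
    target <- v_base * scale_rxn * jitter
    proj <- qp_box(target, S, rep(0, nrow(S)), lb, ub)
    if (proj$status != "optimal") stop("ground-truth projection failed", call. = FALSE)
    flux[, s] <- proj$v
  }
  resid <- max(abs(S %*% flux))
  if (resid > 1e-8) stop("ground truth violates steady state", call. = FALSE)

  active <- lapply(config$states, function(s) rx_ids[abs(flux[, s]) > 1e-6])
  names(active) <- config$states
  planted <- list(
    ald_path = config$ald_order,
    nald_path = config$nald_order,
    branch_point = "healthy",
    chain_reactions = pathways$reaction[pathways$role_class == "ald_chain"],
    nald_reactions = pathways$reaction[pathways$role_class == "nald_chain"],
    ald_only_reactions = pathways$reaction[pathways$role_class == "ald_only"],
    dormant_reactions = pathways$reaction[pathways$role_class == "dormant"])
  structure(list(flux = flux, active = active, multipliers = mult,
                 planted = planted),
            class = "ground_truth")
}

#' Generate a noisy RNA-seq count matrix tied to ground-truth activity
#'
#' Every gene of a reaction gets a designed state-level TPM proportional
#' to the reaction's ground-truth flux magnitude (`tpm_per_flux` per
#' unit), floored at `inactive_tpm` for inactive reactions — so noiseless
#' GPR scores exceed the 1-TPM threshold exactly for active reactions.
#' Background genes (log-normal means, constant across states) fill the
#' library so designed TPMs live on the absolute transcripts-per-million
#' scale; designed TPMs are renormalized per state to sum to one million.
#' Counts are negative-binomial around the expected count implied by gene
#' length and library size (`dispersion = 0` returns the expectation).
#'
#' @param sim output of [generate_model()].
#' @param truth a `ground_truth` from [generate_state_fluxes()].
#' @param config the same `simulation_config`.
#' @param lib_size library size per sample (default 1e6).
#' @return `expression_matrix` object; attribute `"designed_tpm"` holds
#'   the designed gene x state TPM means.
#' @export
generate_expression <- function(sim, truth, config = simulation_config(),
                                lib_size = 1e6) {
  set.seed(config$seed + 2L)
  model <- sim$model
  # gene -> reaction map (genes are dedicated per reaction by construction)
  gene_rxn <- list()
  for (i in seq_len(nrow(model$reactions))) {
    g <- gpr_genes(parse_gpr(model$reactions$gpr[i]))
    for (gg in g) gene_rxn[[gg]] <- model$reactions$id[i]
  }
  model_genes <- model$genes
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  all_genes <- c(model_genes, bg_genes)

  raw <- matrix(0, nrow = length(all_genes), ncol = length(config$states),
                dimnames = list(all_genes, config$states))
  for (g in model_genes) {
    v <- abs(truth$flux[gene_rxn[[g]], ])
    raw[g, ] <- pmax(config$inactive_tpm, config$tpm_per_flux * v)
  }
  bg_means <- stats::rlnorm(length(bg_genes), meanlog = log(100), sdlog = 1)
  model_sum <- mean(colSums(raw[model_genes, , drop = FALSE]))
  bg_means <- bg_means * (1e6 - model_sum) / sum(bg_means)
  raw[bg_genes, ] <- matrix(rep(bg_means, length(config$states)),
                            ncol = length(config$states))
  designed <- sweep(raw, 2, colSums(raw), "/") * 1e6

  lengths <- stats::setNames(
    round(exp(stats::runif(length(all_genes), log(500), log(5000)))), all_genes)

  sample_ids <- unlist(lapply(config$states, function(s)
    sprintf("%s_s%02d", s, seq_len(config$samples_per_state[[s]]))))
  sample_state <- stats::setNames(
    rep(config$states, times = config$samples_per_state[config$states]),
    sample_ids)

  counts <- matrix(0, nrow = length(all_genes), ncol = length(sample_ids),
                   dimnames = list(all_genes, sample_ids))
  for (smp in sample_ids) {
    tpm_s <- designed[, sample_state[[smp]]]
    p <- (tpm_s * lengths) / sum(tpm_s * lengths)
    mu <- lib_size * p
    counts[, smp] <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else mu
  }
  em <- expression_matrix(counts, sample_state, lengths = lengths, model = model)
  attr(em, "designed_tpm") <- designed
  em
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: model + tasks, ground-truth fluxes, expression.
#'
#' @param config a `simulation_config`.
#' @return list: `model`, `tasks`, `pathways`, `capacities`, `truth`,
#'   `expression`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sim <- generate_model(config)
  truth <- generate_state_fluxes(sim, config)
  expr <- generate_expression(sim, truth, config)
  c(sim, list(truth = truth, expression = expr, config = config))
}
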
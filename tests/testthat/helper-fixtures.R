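# Fixtures and independent oracles, all built in code.

# --- toy models ------------------------------------------------------------

# linear chain ->A (no GPR), A->B (G1), B-> (G2); the canonical hand case
toy_chain_model <- function(ub_in = 10) {
  metabolic_model(
    id = "chain",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "R_AB", "EX_B"), name = c("EX_A", "R_AB", "EX_B"),
      lower_bound = 0, upper_bound = c(ub_in, 1000, 1000),
      subsystem = "core", gpr = c("", "G1", "G2")),
    stoichiometry = list(EX_A = c(A_c = 1), R_AB = c(A_c = -1, B_c = 1),
                         EX_B = c(B_c = -1)),
    genes = c("G1", "G2"))
}

# two parallel A->B routes with equal expression; stage-1 FBA is degenerate
# and the l2 step must return the equal split
toy_diamond_model <- function() {
  metabolic_model(
    id = "diamond",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "EX_B"),
      name = c("EX_A", "R1", "R2", "EX_B"),
      lower_bound = 0, upper_bound = c(4, 1000, 1000, 1000),
      subsystem = "core", gpr = c("", "G1", "G2", "")),
    stoichiometry = list(EX_A = c(A_c = 1), R1 = c(A_c = -1, B_c = 1),
                         R2 = c(A_c = -1, B_c = 1), EX_B = c(B_c = -1)),
    genes = c("G1", "G2"))
}

# an n-step linear pathway EX_in -> S1 .. Sk -> EX_out, every internal
# reaction carrying a single dedicated gene
toy_path_model <- function(n_internal = 3, ub = 10) {
  mets <- sprintf("M%d_c", seq_len(n_internal + 1))
  rx_ids <- c("EX_in", sprintf("S%d", seq_len(n_internal)), "EX_out")
  st <- c(list(EX_in = stats::setNames(1, mets[1])),
          stats::setNames(lapply(seq_len(n_internal), function(i) {
            stats::setNames(c(-1, 1), mets[c(i, i + 1)])
          }), sprintf("S%d", seq_len(n_internal))),
          list(EX_out = stats::setNames(-1, mets[n_internal + 1])))
  genes <- sprintf("g%d", seq_len(n_internal))
  metabolic_model(
    id = "path",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(id = mets, name = sub("_c$", "", mets),
                             compartment = "c"),
    reactions = data.frame(
      id = rx_ids, name = rx_ids, lower_bound = 0,
      upper_bound = c(ub, rep(1000, n_internal), 1000),
      subsystem = "core", gpr = c("", genes, "")),
    stoichiometry = st, genes = genes)
}

toy_path_task <- function(model) {
  first_met <- names(model$stoichiometry$EX_in)
  last_met <- names(model$stoichiometry$EX_out)
  metabolic_task("T_path",
                 inputs = list(list(metabolite = first_met, max = 10)),
                 outputs = list(list(metabolite = last_met, min = 0.1)))
}

# build a context_model directly from a kept reaction set
manual_context <- function(model, kept, state = "test") {
  kept <- intersect(model$reactions$id, kept)
  structure(list(parent_id = model$id, state = state, kept_reactions = kept,
                 provenance = stats::setNames(
                   rep("expression_supported", length(kept)), kept),
                 threshold = 1),
            class = "context_model")
}

# --- GPR oracles -----------------------------------------------------------

# random GPR tree over a gene pool; depth-bounded
random_gpr_tree <- function(genes, depth) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(structure(list(gene = sample(genes, 1)), class = "gpr_tree"))
  }
  op <- sample(c("AND", "OR"), 1)
  n_kids <- sample(2:3, 1)
  structure(list(op = op, children = lapply(seq_len(n_kids), function(i)
    random_gpr_tree(genes, depth - 1))), class = "gpr_tree")
}

# fully parenthesized rendering (no reliance on precedence)
render_full_parens <- function(node) {
  if (!is.null(node$gene)) return(node$gene)
  inner <- vapply(node$children, render_full_parens, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", node$op, " ")), ")")
}

# independent brute-force evaluator (deliberately not the package's walker)
brute_eval_gpr <- function(node, vals) {
  if (!is.null(node$gene)) return(unname(vals[node$gene]))
  xs <- sapply(node$children, brute_eval_gpr, vals = vals)
  if (node$op == "AND") min(xs) else max(xs)
}

# --- Wilcoxon enumeration oracle ------------------------------------------

# exact two-sided rank-sum p by full enumeration of rank assignments
# (untied data): p = min(1, 2 * min(P(W <= w), P(W >= w)))
enum_wilcoxon_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  sets <- utils::combn(N, n)
  ws <- colSums(matrix(seq_len(N)[sets], nrow = n))
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- MST brute-force oracle ------------------------------------------------

# decode a Pruefer sequence into an edge list (labels 1..n)
pruefer_decode <- function(pruefer, n) {
  degree <- rep(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  k <- 1L
  for (v in pruefer) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, v); k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  rest <- which(degree == 1L)
  edges[k, ] <- rest
  edges
}

# minimum spanning-tree weight by enumerating all n^(n-2) labeled trees
brute_mst_weight <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    edges <- pruefer_decode(seqs[i, ], n)
    w <- sum(D[edges])
    if (w < best) best <- w
  }
  best
}

# --- structural-mirror fixture (divergent-subsystem proportions) -----------

# parent with one divergent subsystem: 64 reactions that differ between two
# context models, 61 of them ruled, collapsing to 14 unique rules; plus 6
# reactions common to every model
mirror_fixture <- function() {
  n_diff <- 64; n_ruled <- 61; n_rules <- 14; n_common <- 6
  n <- n_diff + n_common
  mets <- sprintf("m%03d_c", seq_len(n + 1))
  rx_ids <- sprintf("SR%03d", seq_len(n))
  st <- stats::setNames(lapply(seq_len(n), function(i) {
    stats::setNames(c(-1, 1), mets[c(i, i + 1)])
  }), rx_ids)
  # rule template: 14 unique rules spread over the 61 ruled reactions
  rule_pool <- c(sprintf("SPG%d", 1:10),
                 "SPG11 AND SPG12", "SPG13 OR SPG14",
                 "SPG15 AND SPG16", "SPG17 OR SPG18")
  counts <- c(rep(4, 9), rep(5, 5))  # 9*4 + 5*5 = 61
  rules_diff <- c(rep(rule_pool, times = counts), rep("", n_diff - n_ruled))
  gprs <- c(rules_diff, rep("SPGC", n_common))
  genes <- c(sprintf("SPG%d", 1:18), "SPGC")
  parent <- metabolic_model(
    id = "mirror",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(id = mets, name = sub("_c$", "", mets),
                             compartment = "c"),
    reactions = data.frame(id = rx_ids, name = rx_ids, lower_bound = 0,
                           upper_bound = 1000,
                           subsystem = "Sphingolipid metabolism", gpr = gprs),
    stoichiometry = st, genes = genes)
  common_ids <- rx_ids[(n_diff + 1):n]
  m_full <- manual_context(parent, rx_ids, state = "full")
  m_core <- manual_context(parent, common_ids, state = "core")
  list(parent = parent, models = list(m_full, m_core))
}

# transport cluster mirroring the dominant-rule proportions: 230 reactions,
# 89 of which share one rule
cluster_fixture <- function() {
  n <- 230; n_top <- 89
  mets <- c(sprintf("t%03d_e", seq_len(n)), sprintf("t%03d_c", seq_len(n)))
  rx_ids <- sprintf("TRX%03d", seq_len(n))
  st <- stats::setNames(lapply(seq_len(n), function(i) {
    stats::setNames(c(-1, 1), c(sprintf("t%03d_e", i), sprintf("t%03d_c", i)))
  }), rx_ids)
  other_rules <- sprintf("SLCX%d", seq_len(40))
  gprs <- c(rep("SLC7A5", n_top),
            rep(other_rules, length.out = n - n_top))
  genes <- c("SLC7A5", other_rules)
  model <- metabolic_model(
    id = "transport_cluster",
    compartments = data.frame(id = c("e", "c"),
                              name = c("extracellular", "cytosol")),
    metabolites = data.frame(
      id = mets, name = sub("_[ec]$", "", mets),
      compartment = rep(c("e", "c"), each = n)),
    reactions = data.frame(id = rx_ids, name = rx_ids, lower_bound = 0,
                           upper_bound = 1000,
                           subsystem = "Transport reactions", gpr = gprs),
    stoichiometry = st, genes = genes)
  list(model = model,
       clusters = stats::setNames(rep(1L, n), rx_ids))
}

# --- random scored context models (flux-contract sweeps) -------------------

random_context_case <- function(seed) {
  cfg <- simulation_config(seed = seed, n_reactions = 25L)
  sim <- generate_model(cfg)
  model <- sim$model
  set.seed(seed + 1000L)
  gene_vals <- stats::setNames(stats::runif(length(model$genes), 0, 5),
                               model$genes)
  scores <- score_reactions(model, gene_vals)
  context <- threshold_extract(model, scores, threshold = 0.5)
  list(sim = sim, model = model, scores = scores, context = context)
}
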
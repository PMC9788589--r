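make_scores <- function(model, values) {
  ruled <- model$reactions$id[nzchar(model$reactions$gpr)]
  structure(list(state = "t",
                 scores = values[ruled],
                 no_gpr = model$reactions$id[!nzchar(model$reactions$gpr)]),
            class = "reaction_scores")
}

test_that("threshold extraction is strict and tags provenance", {
  m <- toy_path_model(3)
  sc <- make_scores(m, c(S1 = 1.5, S2 = 1.0, S3 = 0.2))
  ctx <- threshold_extract(m, sc, threshold = 1)
  kept_expr <- names(ctx$provenance)[ctx$provenance == "expression_supported"]
  expect_equal(kept_expr, "S1")           # S2 = 1.0 excluded: strict >
  expect_setequal(names(ctx$provenance)[ctx$provenance == "no_gpr_retained"],
                  c("EX_in", "EX_out"))
  # all scores zero: only rule-less reactions kept
  ctx0 <- threshold_extract(m, make_scores(m, c(S1 = 0, S2 = 0, S3 = 0)))
  expect_setequal(ctx0$kept_reactions, c("EX_in", "EX_out"))
  # threshold 0 with positive scores keeps everything
  ctxall <- threshold_extract(m, make_scores(m, c(S1 = 1, S2 = 2, S3 = 3)),
                              threshold = 0)
  expect_setequal(ctxall$kept_reactions, m$reactions$id)
  # dropping rule-less reactions on request
  ctxng <- threshold_extract(m, sc, keep_no_gpr = FALSE)
  expect_equal(ctxng$kept_reactions, "S1")
  # every kept reaction has exactly one provenance tag
  expect_setequal(names(ctx$provenance), ctx$kept_reactions)
})

test_that("lowering the threshold never shrinks the kept set", {
  m <- toy_path_model(5)
  set.seed(3)
  vals <- stats::setNames(stats::runif(5, 0, 3), sprintf("S%d", 1:5))
  sc <- make_scores(m, vals)
  thresholds <- c(2.5, 2, 1.5, 1, 0.5, 0)
  kept_prev <- character(0)
  for (th in thresholds) {
    kept <- threshold_extract(m, sc, threshold = th)$kept_reactions
    expect_true(all(kept_prev %in% kept))
    kept_prev <- kept
  }
})

test_that("task feasibility distinguishes connected, cut, and closed networks", {
  m <- toy_path_model(2)
  task <- toy_path_task(m)
  res <- check_task(m, task)
  expect_true(res$feasible)
  expect_true(all(res$witness[c("S1", "S2")] > 0))
  expect_lte(res$residual, 1e-6)
  # cut the path: infeasible
  ctx_cut <- manual_context(m, setdiff(m$reactions$id, "S1"))
  expect_false(check_task(ctx_cut, task, parent = m)$feasible)
  # closed network with no allowed input cannot satisfy a demand
  closed <- metabolic_task("closed", inputs = list(),
                           outputs = list(list(metabolite = "M3_c", min = 1)))
  ctx_noin <- manual_context(m, setdiff(m$reactions$id, "EX_in"))
  expect_false(check_task(ctx_noin, closed, parent = m)$feasible)
  expect_error(
    check_task(m, metabolic_task("bad", list(),
                                 list(list(metabolite = "NOPE", min = 1)))),
    "unknown metabolites")
})

test_that("gap fill finds exact minimal rescue sets with lexicographic ties", {
  m <- toy_path_model(3)
  task <- toy_path_task(m)
  # single missing link: rescue set is exactly that reaction
  ctx <- manual_context(m, setdiff(m$reactions$id, "S2"))
  filled <- gap_fill(ctx, m, list(task))
  expect_equal(names(filled$provenance)[filled$provenance == "task_rescued"],
               "S2")
  # nothing missing: fixed point
  full <- manual_context(m, m$reactions$id)
  filled2 <- gap_fill(full, m, list(task))
  expect_identical(filled2$kept_reactions, full$kept_reactions)
  expect_false(any(filled2$provenance == "task_rescued"))
  # two parallel rescuing routes of equal cardinality: lexicographically
  # smaller reaction id wins
  dm <- toy_diamond_model()
  dtask <- metabolic_task("d", inputs = list(list(metabolite = "A_c", max = 10)),
                          outputs = list(list(metabolite = "B_c", min = 0.1)))
  dctx <- manual_context(dm, c("EX_A", "EX_B"))
  dfilled <- gap_fill(dctx, dm, list(dtask))
  expect_equal(names(dfilled$provenance)[dfilled$provenance == "task_rescued"],
               "R1")
  # a task infeasible on the parent is an error
  impossible <- metabolic_task("imp", inputs = list(),
                               outputs = list(list(metabolite = "M1_c", min = 1e5)))
  expect_error(gap_fill(ctx, m, list(impossible)), "parent")
})

test_that("after gap fill every task passes on every context model", {
  set.seed(9)
  for (i in 1:5) {
    m <- toy_path_model(sample(2:4, 1))
    task <- toy_path_task(m)
    drop <- sample(grep("^S", m$reactions$id, value = TRUE),
                   sample(1:2, 1))
    ctx <- manual_context(m, setdiff(m$reactions$id, drop))
    filled <- gap_fill(ctx, m, list(task))
    expect_true(check_task(filled, task, parent = m)$feasible)
  }
})

test_that("planted low-scoring subsystems only re-enter through task rescue", {
  cfg <- simulation_config(seed = 5, n_reactions = 30L)
  sim <- generate_model(cfg)
  m <- sim$model
  # score everything in the GSH chain far below threshold, the rest high
  vals <- stats::setNames(rep(5, length(m$genes)), m$genes)
  chain_rx <- sim$pathways$reaction[sim$pathways$pathway == "P1"]
  chain_genes <- unlist(lapply(chain_rx, function(r) {
    gpr_genes(parse_gpr(m$reactions$gpr[m$reactions$id == r]))
  }))
  vals[chain_genes] <- 0.2
  sc <- score_reactions(m, vals)
  ctx <- threshold_extract(m, sc)
  ruled_chain <- intersect(chain_rx, names(sc$scores))
  expect_false(any(ruled_chain %in% ctx$kept_reactions))
  filled <- gap_fill(ctx, m, sim$tasks)
  reentered <- intersect(ruled_chain, filled$kept_reactions)
  expect_true(all(filled$provenance[reentered] == "task_rescued"))
})
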
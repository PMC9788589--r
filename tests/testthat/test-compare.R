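test_that("presence matrix covers the union and agrees with set algebra", {
  m <- toy_path_model(3)
  m1 <- manual_context(m, c("EX_in", "S1"), state = "m1")
  m2 <- manual_context(m, c("S1", "S2"), state = "m2")
  pm <- presence_matrix(list(m1, m2))
  expect_equal(dim(pm), c(3L, 2L))
  expect_equal(pm["EX_in", ], c(m1 = 1L, m2 = 0L))
  expect_equal(pm["S1", ], c(m1 = 1L, m2 = 1L))
  expect_equal(pm["S2", ], c(m1 = 0L, m2 = 1L))
  # identical models give identical columns
  pm2 <- presence_matrix(list(m1, manual_context(m, c("EX_in", "S1"), "m1b")))
  expect_equal(unname(pm2[, 1]), unname(pm2[, 2]))
  # different parents refuse to combine
  other <- manual_context(toy_chain_model(), "EX_A", state = "o")
  expect_error(presence_matrix(list(m1, other)), "different parents")

  # random pairs vs a direct set-algebra oracle
  set.seed(21)
  ids <- m$reactions$id
  for (i in 1:50) {
    a <- sample(ids, sample(1:5, 1)); b <- sample(ids, sample(1:5, 1))
    pmr <- presence_matrix(list(manual_context(m, a, "a"),
                                manual_context(m, b, "b")))
    expect_equal(sum(pmr[, "a"] == 1 & pmr[, "b"] == 1),
                 length(intersect(a, b)))
    expect_equal(nrow(pmr), length(union(a, b)))
  }
})

test_that("Hamming similarity counts disagreements over the union rows", {
  mat <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(1, 0, 1, 0))
  rownames(mat) <- sprintf("r%d", 1:4)
  sim <- hamming_similarity(mat)
  expect_equal(sim["a", "b"], 1.0)
  expect_equal(sim["a", "c"], 0.5)
  expect_true(isSymmetric(sim))
  expect_equal(unname(diag(sim)), rep(1, 3))

  # random instance vs brute-force counting, plus the scaled-metric
  # triangle inequality on distances
  set.seed(8)
  for (rep in 1:20) {
    rmat <- matrix(rbinom(100, 1, 0.5), nrow = 20,
                   dimnames = list(sprintf("r%d", 1:20), sprintf("m%d", 1:5)))
    s <- hamming_similarity(rmat)
    for (a in 1:5) for (b in 1:5) {
      expect_equal(s[a, b], 1 - sum(rmat[, a] != rmat[, b]) / 20)
    }
    d <- 1 - s
    for (x in 1:5) for (y in 1:5) for (z in 1:5) {
      expect_lte(d[x, z], d[x, y] + d[y, z] + 1e-12)
    }
  }
})

test_that("model ranking uses mean ranks for ties and canonical rules", {
  m <- toy_path_model(4)
  big <- manual_context(m, m$reactions$id, "big")
  small <- manual_context(m, c("EX_in", "S1", "EX_out"), "small")
  small2 <- manual_context(m, c("EX_in", "S2", "EX_out"), "small2")
  rk <- rank_models(list(big, small, small2), m)
  expect_equal(rk$rank_reactions[rk$model == "big"], 1)
  expect_equal(rk$rank_reactions[rk$model %in% c("small", "small2")],
               c(2.5, 2.5))
  # operand order does not inflate the unique-rule count
  m2 <- toy_path_model(2)
  m2$reactions$gpr[2:3] <- c("g1 AND g2", "g2 AND g1")
  m2$genes <- c("g1", "g2")
  ctx <- manual_context(m2, m2$reactions$id, "x")
  ctx2 <- manual_context(m2, m2$reactions$id, "y")
  rk2 <- rank_models(list(ctx, ctx2), m2)
  expect_equal(rk2$unique_gene_rules, c(1, 1))
})

test_that("subsystem coverage screen flags >10% pairwise differences", {
  m <- toy_path_model(10)
  m$reactions$subsystem <- c("exch", rep("alpha", 6), rep("beta", 4))[
    seq_len(nrow(m$reactions))]
  all_ids <- m$reactions$id
  alpha_ids <- all_ids[m$reactions$subsystem == "alpha"]
  # alpha: 6 vs 4 reactions (33% diff) -> flagged; beta identical -> not
  ma <- manual_context(m, all_ids, "ma")
  mb <- manual_context(m, setdiff(all_ids, alpha_ids[1:2]), "mb")
  ds <- differential_subsystems(list(ma, mb), m)
  expect_true(ds$flagged[ds$subsystem == "alpha"])
  expect_false(ds$flagged[ds$subsystem == "beta"])
  expect_equal(ds$common[ds$subsystem == "alpha"], 4)
  # 10 vs 12 -> 16.7% flagged; 100 vs 105 -> 4.8% not flagged
  expect_true(abs(10 - 12) / 12 > 0.10)
  expect_false(abs(100 - 105) / 105 > 0.10)
  # invariant to model ordering
  ds2 <- differential_subsystems(list(mb, ma), m)
  expect_equal(ds$max_rel_diff_pct, ds2$max_rel_diff_pct)
})

test_that("gene-rule drilldown reports differing reactions and z-scores", {
  fx <- mirror_fixture()
  dd <- gene_rule_drilldown(fx$models, fx$parent, "Sphingolipid metabolism")
  expect_equal(dd$n_differing, 64)
  expect_equal(dd$n_with_rules, 61)
  expect_equal(dd$n_unique_rules, 14)
  # a reaction present in all models never appears
  common_rule_rows <- grepl("SPGC", dd$rules$rule)
  expect_false(any(common_rule_rows))
  expect_error(gene_rule_drilldown(fx$models, fx$parent, "Nope"), "absent")
  # constant-across-states gene expression z-scores to zero
  profs <- list(
    A = structure(list(state = "A", gene_values = c(SPG1 = 2, SPG2 = 1)),
                  class = "state_profile"),
    B = structure(list(state = "B", gene_values = c(SPG1 = 2, SPG2 = 3)),
                  class = "state_profile"))
  dd2 <- gene_rule_drilldown(fx$models, fx$parent, "Sphingolipid metabolism",
                             state_profiles = profs)
  expect_equal(unname(dd2$gene_zscores["SPG1", ]), c(0, 0))
  expect_equal(unname(dd2$gene_zscores["SPG2", ]),
               c(-1, 1) / sqrt(2))  # z of {1,3}: (x - 2)/sd, sd = sqrt(2)
})
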
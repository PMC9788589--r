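test_that("subsystem sums follow the magnitude convention", {
  m <- toy_path_model(3)
  m$reactions$subsystem <- c("exch", "alpha", "alpha", "beta", "exch")
  tab <- matrix(c(1, -2, 0.5, 3, 0.1, 1, 1, 1, 1, 1), ncol = 2,
                dimnames = list(m$reactions$id, c("A", "B")))
  res <- subsystem_flux_sums(tab, m)
  expect_equal(unname(res$sums["alpha", "A"]), 2.5)  # |-2| + |0.5|
  expect_equal(unname(res$sums["beta", "A"]), 3)
  signed <- subsystem_flux_sums(tab, m, signed = TRUE)
  expect_equal(unname(signed$sums["alpha", "A"]), -1.5)
  # permutation invariance
  perm <- sample(nrow(tab))
  res2 <- subsystem_flux_sums(tab[perm, , drop = FALSE], m)
  expect_equal(res$sums, res2$sums[rownames(res$sums), , drop = FALSE])
  expect_error(subsystem_flux_sums(
    matrix(1, 1, 1, dimnames = list("ghost", "A")), m), "unknown")
})

test_that("Wilcoxon rank-sum matches enumeration exactly on untied data", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)  # 2 * (1/20) over C(6,3) rank assignments
  expect_equal(w$statistic, 6)  # minimal rank sum for x
  expect_true(w$exact)
  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")

  # full enumeration sweep over all untied size configurations n + m <= 10
  set.seed(33)
  for (n in 1:8) for (m in 1:(10 - n)) {
    if (m < 1) next
    for (rep in 1:3) {
      vals <- sample(seq(1, 100, by = 0.5), n + m)  # distinct values
      x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
      expect_equal(wilcoxon_rank_sum(x, y)$p_value, enum_wilcoxon_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
  # large-sample approximation agrees with enumeration at n = m = 8
  set.seed(34)
  vals <- sample(seq(1, 200, 0.5), 16)
  x <- vals[1:8]; y <- vals[9:16]
  w8 <- wilcoxon_rank_sum(x, y)
  expect_true(w8$exact)
  expect_equal(w8$p_value, enum_wilcoxon_p(x, y), tolerance = 1e-12)
})

test_that("the subsystem screen flags planted flux shifts and respects alpha", {
  m <- toy_path_model(10)
  m$reactions$subsystem <- c("exch", rep("planted", 10), "exch")
  set.seed(40)
  base <- stats::runif(10, 1, 2)
  tab <- cbind(A = c(0, base, 0), B = c(0, base * 2, 0))
  rownames(tab) <- m$reactions$id
  scr <- suppressWarnings(subsystem_screen(tab, m, alpha = 0.05))
  expect_true(scr$table$flagged[scr$table$subsystem == "planted"])
  # identical states are never flagged
  tab_same <- cbind(A = c(0, base, 0), B = c(0, base, 0))
  rownames(tab_same) <- m$reactions$id
  scr_same <- suppressWarnings(subsystem_screen(tab_same, m))
  expect_false(any(scr_same$table$flagged))
  # alpha = 0 flags nothing
  scr0 <- suppressWarnings(subsystem_screen(tab, m, alpha = 0))
  expect_false(any(scr0$table$flagged))
  # subsystems with < 2 reactions are skipped with a warning
  m2 <- toy_path_model(2)
  m2$reactions$subsystem <- c("a", "b", "c", "a")
  tab2 <- matrix(1, 4, 2, dimnames = list(m2$reactions$id, c("A", "B")))
  expect_warning(expect_warning(subsystem_screen(tab2, m2), "skipped"), "skipped")
})

test_that("hierarchical clustering separates orthogonal patterns deterministically", {
  pa <- c(1, 2, 3, 4, 5, 6)
  pb <- c(6, 5, 4, 3, 2, 1)
  mat <- rbind(a1 = pa, a2 = pa + 0.1, b1 = pb, b2 = pb - 0.1)
  colnames(mat) <- sprintf("s%d", 1:6)
  cl <- hierarchical_cluster(mat, k = 2)
  expect_equal(cl$cluster[["a1"]], cl$cluster[["a2"]])
  expect_equal(cl$cluster[["b1"]], cl$cluster[["b2"]])
  expect_true(cl$cluster[["a1"]] != cl$cluster[["b1"]])
  # k = 1: everything together
  expect_equal(unname(hierarchical_cluster(mat, 1)$cluster), rep(1L, 4))
  # duplicated rows merge first and never split
  mat2 <- rbind(mat, a1copy = pa)
  cl2 <- hierarchical_cluster(mat2, k = 2)
  expect_equal(cl2$cluster[["a1"]], cl2$cluster[["a1copy"]])
  expect_error(hierarchical_cluster(mat, k = 9), "exceeds")
  # permutation invariance up to relabeling
  perm <- c(3, 1, 4, 2)
  cl3 <- hierarchical_cluster(mat[perm, ], k = 2)
  agree <- outer(cl$cluster[rownames(mat)], cl$cluster[rownames(mat)], "==")
  agree3 <- outer(cl3$cluster[rownames(mat)], cl3$cluster[rownames(mat)], "==")
  expect_equal(agree, agree3)
})

test_that("gene-rule frequencies count canonical rules per cluster", {
  m <- toy_path_model(3)
  m$reactions$gpr <- c("", "gA", "gA", "gB", "")
  m$genes <- c("gA", "gB")
  cl <- stats::setNames(c(1L, 1L, 1L), c("S1", "S2", "S3"))
  fr <- gene_rule_frequency(cl, m)
  expect_equal(fr$most_frequent$rule, "gA")
  expect_equal(fr$most_frequent$count, 2L)
  expect_equal(fr$most_frequent$fraction, 2 / 3)
  # shuffling reaction order reproduces the fractions
  fr2 <- gene_rule_frequency(cl[c(3, 1, 2)], m)
  expect_equal(fr$table$fraction, fr2$table$fraction)
  # the dominant-rule mirror: 89 of 230 transport reactions share one rule
  fx <- cluster_fixture()
  frm <- gene_rule_frequency(fx$clusters, fx$model)
  expect_equal(frm$most_frequent$rule, "SLC7A5")
  expect_equal(frm$most_frequent$count, 89L)
  expect_equal(frm$most_frequent$fraction, 89 / 230)
  # empty cluster assignment gives empty tables
  fr0 <- gene_rule_frequency(stats::setNames(integer(0), character(0)), m)
  expect_equal(nrow(fr0$table), 0)
})

test_that("transport direction mapping orients by flux sign and drops mixed species", {
  m <- metabolic_model(
    id = "tr",
    compartments = data.frame(id = c("e", "c"), name = c("ext", "cyt")),
    metabolites = data.frame(
      id = c("A_e", "A_c", "B_e", "B_c"),
      name = c("A", "A", "B", "B"),
      compartment = c("e", "c", "e", "c")),
    reactions = data.frame(
      id = c("TR_A", "TR_B1", "TR_B2", "R_int"),
      name = c("TR_A", "TR_B1", "TR_B2", "R_int"),
      lower_bound = -10, upper_bound = 10, subsystem = "Transport",
      gpr = ""),
    stoichiometry = list(TR_A = c(A_e = -1, A_c = 1),
                         TR_B1 = c(B_e = -1, B_c = 1),
                         TR_B2 = c(B_c = -1, B_e = 1),
                         R_int = c(A_c = -1, B_c = 1)),
    genes = character(0))
  # forward flux on A[e] -> A[c]: import
  res <- transport_direction_map("TR_A", m, c(TR_A = 1))
  expect_equal(res$kept$direction, "import")
  # reversed flux: export
  res2 <- transport_direction_map("TR_A", m, c(TR_A = -1))
  expect_equal(res2$kept$direction, "export")
  # species imported by one reaction and exported by another is dropped
  res3 <- transport_direction_map(c("TR_B1", "TR_B2"), m,
                                  c(TR_B1 = 1, TR_B2 = 1))
  expect_equal(res3$dropped_mixed, "B")
  expect_equal(nrow(res3$kept), 0)
  expect_error(transport_direction_map("R_int", m, c(R_int = 1)),
               "not transport")
})
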
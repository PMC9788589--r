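chain_scores <- function(model) {
  structure(list(state = "t", scores = c(R_AB = 3, EX_B = 2), no_gpr = "EX_A"),
            class = "reaction_scores")
}

test_that("SPOT recovers the hand-derived chain direction and cosine", {
  m <- toy_chain_model()
  spot <- spot_objective(m, chain_scores(m))
  # feasible cone is the ray (1,1,1): cosine = (5/sqrt(3))/sqrt(13)
  expect_equal(spot$achieved_cosine, 5 / sqrt(3) / sqrt(13), tolerance = 1e-8)
  expect_equal(unname(spot$f_prime), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  expect_false(spot$degenerate)
  expect_equal(sqrt(sum(spot$f_prime^2)), 1, tolerance = 1e-8)
})

test_that("SPOT is scale-invariant and degenerates gracefully at g = 0", {
  m <- toy_chain_model()
  s1 <- chain_scores(m)
  s10 <- s1; s10$scores <- 10 * s10$scores
  sp1 <- spot_objective(m, s1); sp10 <- spot_objective(m, s10)
  expect_equal(sp1$f_prime, sp10$f_prime, tolerance = 1e-6)
  expect_equal(sp1$achieved_cosine, sp10$achieved_cosine, tolerance = 1e-6)
  s0 <- s1; s0$scores[] <- 0
  sp0 <- spot_objective(m, s0)
  expect_true(sp0$degenerate)
  expect_equal(sp0$achieved_cosine, 0)
  expect_equal(unname(sp0$f_prime), rep(0, 3))
})

test_that("SPOT beats random feasible directions (optimality oracle)", {
  set.seed(14)
  for (model_i in 1:10) {
    cfg <- simulation_config(seed = model_i, n_reactions = 20L)
    sim <- generate_model(cfg)
    m <- sim$model
    gene_vals <- stats::setNames(stats::runif(length(m$genes), 0, 5), m$genes)
    sc <- score_reactions(m, gene_vals)
    spot <- spot_objective(m, sc)
    # feasible fluxes: non-negative combinations of the unit pathway flows
    pw <- sim$pathways
    for (i in 1:100) {
      u <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
      for (p in unique(pw$pathway)) {
        u[pw$reaction[pw$pathway == p]] <- stats::runif(1, 0, 5)
      }
      expect_lte(spot_cosine(m, sc, u), spot$achieved_cosine + 1e-8)
    }
  }
})

test_that("expression-derived bounds follow the reversibility convention", {
  m <- metabolic_model(
    id = "b",
    compartments = data.frame(id = c("e", "c"), name = c("e", "c")),
    metabolites = data.frame(id = c("A_e", "A_c", "B_c"),
                             name = c("A", "A", "B"),
                             compartment = c("e", "c", "c")),
    reactions = data.frame(
      id = c("R_irr", "R_rev", "TR_nogpr"),
      name = c("R_irr", "R_rev", "TR_nogpr"),
      lower_bound = c(0, -1000, -1000), upper_bound = 1000,
      subsystem = "s", gpr = c("G1", "G2", "")),
    stoichiometry = list(R_irr = c(A_c = -1, B_c = 1),
                         R_rev = c(A_c = -1, B_c = 1),
                         TR_nogpr = c(A_e = -1, A_c = 1)),
    genes = c("G1", "G2"))
  sc <- score_reactions(m, c(G1 = 2.5, G2 = 2.5))
  b <- eflux2_bounds(m, sc)
  expect_equal(b[b$reaction == "R_irr", c("lower", "upper")],
               data.frame(lower = 0, upper = 2.5, row.names = 1L))
  expect_equal(b[b$reaction == "R_rev", c("lower", "upper")],
               data.frame(lower = -2.5, upper = 2.5, row.names = 2L))
  expect_equal(b[b$reaction == "TR_nogpr", c("lower", "upper")],
               data.frame(lower = -1000, upper = 1000, row.names = 3L))
})

test_that("E-Flux2 solves the chain exactly and handles degenerate cases", {
  m <- toy_chain_model()
  sc <- chain_scores(m)
  spot <- spot_objective(m, sc)
  fr <- eflux2_solve(m, spot$f_prime, bounds = eflux2_bounds(m, sc))
  expect_equal(unname(fr$v), c(2, 2, 2), tolerance = 1e-6)
  expect_equal(fr$z_star, 6 / sqrt(3), tolerance = 1e-6)
  expect_lte(fr$residual, 1e-6)
  # all upper bounds zero: only the zero flux is feasible
  b0 <- eflux2_bounds(m, sc)
  b0$upper <- 0; b0$lower <- 0
  fr0 <- eflux2_solve(m, spot$f_prime, bounds = b0)
  expect_equal(unname(fr0$v), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fr0$z_star, 0, tolerance = 1e-9)
})

test_that("the l2 stage resolves stage-1 degeneracy to the equal split", {
  dm <- toy_diamond_model()
  sc <- structure(list(state = "t", scores = c(R1 = 4, R2 = 4),
                       no_gpr = c("EX_A", "EX_B")),
                  class = "reaction_scores")
  spot <- spot_objective(dm, sc)
  fr <- eflux2_solve(dm, spot$f_prime, bounds = eflux2_bounds(dm, sc))
  # EX_A capped at 4 splits equally across the two parallel routes
  expect_equal(unname(fr$v["R1"]), unname(fr$v["R2"]), tolerance = 1e-6)
  expect_equal(unname(fr$v["R1"]), 2, tolerance = 1e-6)
})

test_that("flux results satisfy conservation, bounds, and l2 uniqueness", {
  for (seed in 1:5) {
    case <- random_context_case(seed)
    sc <- case$scores
    spot <- spot_objective(case$context, sc, parent = case$model)
    bounds <- eflux2_bounds(case$context, sc, parent = case$model)
    fr <- eflux2_solve(case$context, spot$f_prime, bounds = bounds,
                       parent = case$model)
    expect_lte(fr$residual, 1e-6)
    sel <- match(names(fr$v), bounds$reaction)
    expect_true(all(fr$v >= bounds$lower[sel] - 1e-6))
    expect_true(all(fr$v <= bounds$upper[sel] + 1e-6))
    # objective preserved through the l2 stage
    f <- stats::setNames(rep(0, length(fr$v)), names(fr$v))
    f[names(spot$f_prime)] <- spot$f_prime
    expect_lte(abs(sum(f * fr$v) - fr$z_star), 1e-6 * max(1, abs(fr$z_star)))
    # permuting the reaction order leaves the solution unchanged
    sub <- context_submodel(case$context, case$model)
    perm <- sample(nrow(sub$reactions))
    sub_p <- subset_model(sub, sub$reactions$id[perm], id = sub$id)
    fr_p <- eflux2_solve(sub_p, spot$f_prime, bounds = bounds)
    expect_lt(max(abs(fr_p$v[names(fr$v)] - fr$v)), 1e-5)
  }
})

test_that("the measurable-flux filter applies the strict magnitude rule", {
  mk <- function(state, v) structure(list(state = state, v = v),
                                     class = "flux_result")
  r1 <- mk("A", c(ra = 0.05, rb = 0.1, rc = 0.2, rd = -0.5))
  tab <- measurable_fluxes(list(r1), threshold = 0.1)
  expect_setequal(rownames(tab), c("rc", "rd"))   # 0.1 itself excluded
  # union rule: above threshold in one state keeps the row everywhere
  r2 <- mk("B", c(ra = 0.0, rb = 0.0, rc = 0.0, rd = 0.0))
  tab2 <- measurable_fluxes(list(r1, r2), threshold = 0.1)
  expect_equal(tab2["rc", "B"], 0)
  expect_setequal(rownames(tab2), c("rc", "rd"))
  expect_warning(measurable_fluxes(list(mk("A", c(r = 0.01)))), "threshold")
})
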
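# LP core: FBA against the vertex-enumeration oracle, FVA, and the
# geometric centring algorithm (symmetry, cycle suppression, determinism,
# mass conservation, linearity).

test_that("solve_lp handles basic bounded LPs", {
  # max x1 + x2 s.t. x1 + x2 <= handled via equality with slack
  res <- solve_lp(c(1, 1, 0), matrix(c(1, 1, 1), 1), 10,
                  c(0, 0, 0), c(6, 6, 10))
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 10)
  # infeasible: x1 = 5 with ub 1
  res <- solve_lp(1, matrix(1, 1, 1), 5, 0, 1)
  expect_equal(res$status, "infeasible")
  # negative bounds
  res <- solve_lp(-1, matrix(1, 1, 1), -3, -10, 10, maximize = FALSE)
  expect_equal(res$x, -3)
})

test_that("toy FBA optimum matches the vertex-enumeration oracle (10/6)", {
  m <- glc_toy(10, with_fa_source = FALSE, extra_sources = FALSE,
               parallel_transport = FALSE)
  expect_equal(oracle_vertex_max(m), 10 / 6, tolerance = 1e-9)
  expect_equal(fba(m)$objective_value, 10 / 6, tolerance = 1e-9)
  # the full default toy reaches the same optimum
  expect_equal(fba(glc_toy(10))$objective_value, 10 / 6, tolerance = 1e-9)
  # LP homogeneity: doubling the uptake doubles the optimum
  expect_equal(fba(glc_toy(20))$objective_value, 20 / 6, tolerance = 1e-9)
})

test_that("closed medium yields zero production and objective is required", {
  m <- toy_model() # all carbon exchanges closed by default
  expect_equal(fba(m)$objective_value, 0)
  m$objective <- numeric()
  expect_error(fba(m), "no objective")
})

test_that("FVA brackets fluxes: parallel transporters, blocked reactions", {
  m <- glc_toy(10)
  rng <- fva(m, fraction_of_optimum = 1,
             reactions = c("GLCt1", "GLCt2", "EX_rl", "FAA"))
  rownames(rng) <- rng$reaction
  # either transporter can carry anything from 0 to the whole uptake
  expect_equal(rng["GLCt1", c("min", "max")],
               data.frame(min = 0, max = 10, row.names = "GLCt1"),
               tolerance = 1e-6)
  expect_equal(rng["GLCt2", c("min", "max")],
               data.frame(min = 0, max = 10, row.names = "GLCt2"),
               tolerance = 1e-6)
  # objective pinned at optimum
  expect_equal(unlist(rng["EX_rl", c("min", "max")]),
               c(min = 10 / 6, max = 10 / 6), tolerance = 1e-6)
  # CoA route blocked without the fatty-acid source
  expect_equal(unlist(rng["FAA", c("min", "max")]), c(min = 0, max = 0),
               tolerance = 1e-9)
  # fraction 0 releases the objective: production exchange spans capability
  rng0 <- fva(m, fraction_of_optimum = 0, reactions = "EX_rl")
  expect_equal(unlist(rng0[1, c("min", "max")]), c(min = 0, max = 10 / 6),
               tolerance = 1e-6)
})

test_that("geometric FBA centres symmetric alternatives and keeps the optimum", {
  m <- glc_toy(10)
  g <- geometric_fba(m)
  expect_true(g$converged)
  expect_equal(g$objective_value, fba(m)$objective_value, tolerance = 1e-9)
  # two identical glucose transporters split the uptake 5/5
  expect_equal(unname(g$fluxes["GLCt1"]), 5, tolerance = 1e-5)
  expect_equal(unname(g$fluxes["GLCt2"]), 5, tolerance = 1e-5)
  # and the rhamnolipid transporters split 10/6 evenly
  expect_equal(unname(g$fluxes["RLt1"]), 5 / 6, tolerance = 1e-5)
  expect_equal(unname(g$fluxes["RLt2"]), 5 / 6, tolerance = 1e-5)
})

test_that("geometric FBA zeroes an isolated thermodynamically infeasible cycle", {
  m <- glc_toy(10, with_loop = TRUE)
  g <- geometric_fba(m)
  expect_equal(max(abs(g$fluxes[c("LOOP1", "LOOP2", "LOOP3")])), 0,
               tolerance = 1e-6)
  # plain FBA may put arbitrary flux around the loop; the optimum is the same
  expect_equal(g$objective_value, 10 / 6, tolerance = 1e-9)
})

test_that("geometric solution is deterministic under reaction reordering", {
  m <- glc_toy(10)
  g1 <- geometric_fba(m, tolerance = 1e-6)
  # permute the reaction order: a different vertex path for the solver
  perm <- rev(seq_len(nrow(m$reactions)))
  m2 <- metabolic_model(m$id, m$metabolites, m$reactions[perm, ],
                        m$stoichiometry[perm], m$objective)
  g2 <- geometric_fba(m2, tolerance = 1e-6)
  expect_lt(max(abs(g1$fluxes[names(g2$fluxes)] - g2$fluxes)), 1e-5)
})

test_that("geometric solution lies inside every FVA range at the optimum", {
  m <- glc_toy(10)
  g <- geometric_fba(m)
  rng <- fva(m, fraction_of_optimum = 1)
  expect_true(all(g$fluxes[rng$reaction] >= rng$min - 1e-6))
  expect_true(all(g$fluxes[rng$reaction] <= rng$max + 1e-6))
})

test_that("optimal solutions conserve mass on all internal metabolites", {
  for (m in list(glc_toy(10), glc_toy(10, with_loop = TRUE),
                 set_medium(toy_model(), c(glucose = 10,
                                           `3-hydroxydecanoate` = 10)))) {
    S <- stoichiometric_matrix(m, sparse = FALSE)
    v <- geometric_fba(m)$fluxes
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= m$reactions$lower_bound - 1e-6))
    expect_true(all(v <= m$reactions$upper_bound + 1e-6))
  }
})

test_that("production scales linearly with uptake rate", {
  base <- fba(glc_toy(1))$objective_value
  for (r in 1:10) {
    expect_equal(fba(glc_toy(r))$objective_value, r * base,
                 tolerance = 1e-9)
  }
})
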
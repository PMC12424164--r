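# FBA solutions, feasibility decisions, grid scans, phenotype screens.

test_that("chain network optimum matches the vertex-enumeration oracle", {
  m <- chain_model(ub = 10)
  sol <- solve_fba(m, "EX_b_e")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-8)
  o <- oracle_lp(as.matrix(m$S), rep(0, n_metabolites(m)),
                 m$reactions$lower_bound, m$reactions$upper_bound,
                 as.numeric(m$reactions$id == "EX_b_e"))
  expect_equal(sol$objective_value, o$value, tolerance = 1e-8)
  # solution satisfies steady state and bounds
  expect_lt(max(abs(as.matrix(m$S) %*% sol$fluxes)), 1e-6)
})

test_that("FBA optimum equals the oracle on small toy subnetworks", {
  # box and chain fixtures at several bound settings (<= 8 reactions)
  for (w in c(0.5, 2, 7)) {
    m <- box_model(w)
    for (obj in m$reactions$id) {
      sol <- solve_fba(m, obj)
      o <- oracle_lp(as.matrix(m$S), rep(0, n_metabolites(m)),
                     m$reactions$lower_bound, m$reactions$upper_bound,
                     as.numeric(m$reactions$id == obj))
      expect_equal(sol$objective_value, o$value, tolerance = 1e-8)
    }
  }
})

test_that("overconstrained biomass is reported infeasible, not zero", {
  m <- make_toy_acetogen()
  # CO supply capped far below what the demanded biomass flux requires
  m <- set_bounds(m, "EX_co_e", lower = -0.1, upper = 0)
  m <- set_bounds(m, "EX_h2_e", upper = 0)
  m <- set_bounds(m, "Biomass", lower = 1, upper = 1)
  sol <- solve_fba(m, "Biomass")
  expect_equal(sol$status, "infeasible")
  expect_true(is.null(sol$fluxes))
})

test_that("feasibility flag matches the FBA outcome", {
  tri <- make_toy_triculture()
  expect_true(check_feasibility(tri, paper_condition()))
  # mu = 0 with zero maintenance: trivially feasible on any feed
  cfg0 <- toy_config(ngam_rate = 0)
  tri0 <- make_toy_triculture(cfg0)
  expect_true(check_feasibility(
    tri0, community_condition(0, 0.32, c(aw = 0.5, an = 0.3, ck = 0.2))))
  # carbon-limited: forced CO uptake exceeds the acetogen transport capacity
  # (vmax 20 mmol/gCDW/h * 0.32 g * 0.05 = 0.32 < forced 2.5 mmol/h)
  tight <- community_condition(0.02, 0.32, c(aw = 0.05, an = 0.05, ck = 0.9),
                               list(EX_co_e = c(-3.5, -2.5)))
  expect_false(check_feasibility(tri, tight))
})

test_that("feasible growth rates form an interval on every ratio row", {
  tri <- make_toy_triculture()
  ratios <- ratio_lattice(c("aw", "an", "ck"), step = 0.2)
  mu_grid <- seq(0.005, 0.08, by = 0.015)
  grid <- scan_feasibility(tri, ratios, mu_grid, 0.32,
                           list(EX_co_e = c(-3.5, -1)))
  M <- attr(grid, "matrix")
  expect_equal(dim(M), c(length(ratios), length(mu_grid)))
  for (i in seq_len(nrow(M))) {
    w <- which(M[i, ])
    expect_true(length(w) == 0 || all(diff(w) == 1))
  }
  # at least one feasible and one infeasible cell under these conditions
  expect_gt(sum(M), 0)
  expect_lt(sum(M), length(M))
})

test_that("a 1x1 grid equals check_feasibility", {
  tri <- make_toy_triculture()
  fr <- c(aw = 0.5, an = 0.3, ck = 0.2)
  g <- scan_feasibility(tri, list(fr), 0.02, 0.32,
                        list(EX_co_e = c(-3.5, -1)))
  expect_equal(nrow(g), 1)
  expect_equal(g$feasible, check_feasibility(tri, paper_condition()))
})

test_that("an all-starved configuration yields an all-false grid", {
  tri <- make_toy_triculture()   # NGAM > 0, so no feed means no steady state
  g <- scan_feasibility(tri, list(c(aw = 0.5, an = 0.3, ck = 0.2)),
                        c(0.01, 0.02), 0.32,
                        list(EX_co_e = c(0, 0), EX_h2_e = c(0, 0)))
  expect_false(any(g$feasible))
})

test_that("phenotype screen reproduces the expected carbon-source calls", {
  aw <- make_toy_acetogen()
  screen <- phenotype_screen(
    aw,
    list(CO = "EX_co_e", "H2+CO2" = c("EX_h2_e", "EX_co2_e"),
         "H2 alone" = "EX_h2_e", fructose = "EX_fructose_e"),
    carbon_sources = c("EX_co_e", "EX_co2_e"))
  grow <- setNames(screen$growth, screen$substrate)
  expect_true(grow[["CO"]])
  expect_true(grow[["H2+CO2"]])
  expect_false(grow[["H2 alone"]])            # no carbon source
  expect_true(is.na(grow[["fructose"]]))      # not representable in the toy
  # all uptakes closed: no growth
  none <- phenotype_screen(aw, list(none = character(0)),
                           carbon_sources = c("EX_co_e", "EX_co2_e",
                                              "EX_h2_e"))
  expect_false(none$growth)
})
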
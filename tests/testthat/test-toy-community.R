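# The synthetic three-species community: elemental balance, degree of
# reduction closure, and the hand-checkable catabolic stoichiometries.

test_that("every internal toy reaction is elementally balanced", {
  for (make in list(make_toy_acetogen, make_toy_propionigen,
                    make_toy_chain_elongator)) {
    rep <- check_elemental_balance(make())
    expect_equal(sum(rep$status == "imbalanced"), 0)
    expect_equal(sum(rep$status == "unchecked"), 0)
  }
  rep <- check_elemental_balance(make_toy_triculture())
  expect_equal(sum(rep$status == "imbalanced"), 0)
})

test_that("degree-of-reduction closure holds for every catabolic lump", {
  # gamma = 4C + H - 2O; element-balanced lumps must satisfy
  # sum(gamma * coefficient) = 0
  gammas <- c(
    degree_of_reduction("C2H6O"),   # ethanol 12
    degree_of_reduction("C4H8O2"),  # butyrate 20
    degree_of_reduction("C5H10O2"), # valerate 26
    degree_of_reduction("C7H14O2")) # heptanoate 38
  expect_equal(gammas, c(12, 20, 26, 38))
  # elongation arithmetic: donor + acceptor = product
  expect_equal(12 + 8, degree_of_reduction("C4H8O2"))     # eth + acetate
  expect_equal(12 + 14, degree_of_reduction("C5H10O2"))   # eth + propionate
  expect_equal(12 + 26, degree_of_reduction("C7H14O2"))   # eth + valerate
  for (make in list(make_toy_acetogen, make_toy_propionigen,
                    make_toy_chain_elongator)) {
    m <- make()
    rep <- check_elemental_balance(m)
    internal <- rep$reaction_id[rep$status == "balanced"]
    for (rid in internal) {
      st <- reaction_stoichiometry(m, rid)
      g <- vapply(names(st), function(mid) {
        f <- m$metabolites$formula[m$metabolites$id == mid]
        degree_of_reduction(f)
      }, numeric(1))
      expect_lt(abs(sum(g * st)), 1e-9)
    }
  }
})

test_that("acetogen on CO alone follows 4 CO + 2 H2O -> acetate + 2 CO2", {
  cfg <- toy_config(ngam_rate = 0)
  m <- make_toy_acetogen(cfg)
  m <- set_bounds(m, "EX_co_e", lower = -4, upper = -4)
  m <- set_bounds(m, "ETOH", upper = 0)
  m <- set_bounds(m, "Biomass", upper = 0)
  sol <- solve_fba(m, "EX_acetate_e")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$fluxes[["EX_acetate_e"]], 1, tolerance = 1e-8)
  expect_equal(sol$fluxes[["EX_co2_e"]], 2, tolerance = 1e-8)
})

test_that("propionigen acrylate route gives propionate:acetate 2:1, tunable down", {
  cfg <- toy_config(ngam_rate = 0)
  m <- make_toy_propionigen(cfg)
  m <- set_bounds(m, "EX_ethanol_e", lower = -3, upper = -3)
  m <- set_bounds(m, "Biomass", upper = 0)
  # pure acrylate flux: block oxidation
  m1 <- set_bounds(m, "ETOX", upper = 0)
  s1 <- solve_fba(m1, "EX_propionate_e")
  expect_equal(s1$fluxes[["EX_propionate_e"]] / s1$fluxes[["EX_acetate_e"]],
               2, tolerance = 1e-8)
  # mixing in oxidation lowers the ratio through 1.2:1
  # with ACR flux a and ETOX flux o: ratio = 2a / (a + o); at o = 2a/3 the
  # ratio is 1.2 and ethanol use is 3a + o
  a <- 0.6; o <- 0.4
  m2 <- set_bounds(m, "EX_ethanol_e", lower = -(3 * a + o), upper = -(3 * a + o))
  m2 <- set_bounds(m2, "ETOX", lower = o, upper = o)
  s2 <- solve_fba(m2, "EX_propionate_e")
  expect_equal(s2$fluxes[["EX_propionate_e"]] / s2$fluxes[["EX_acetate_e"]],
               1.2, tolerance = 1e-6)
})

test_that("propionigen cannot grow without ethanol", {
  m <- make_toy_propionigen()
  m <- set_bounds(m, "EX_ethanol_e", lower = 0)
  sol <- solve_fba(m, "Biomass")
  expect_true(sol$status != "optimal" || sol$objective_value < 1e-9)
})

test_that("chain elongator consumes ethanol and acetate 1:1 for butyrate", {
  cfg <- toy_config(ngam_rate = 0)
  m <- make_toy_chain_elongator(cfg)
  m <- set_bounds(m, "EX_ethanol_e", lower = -2, upper = 0)
  m <- set_bounds(m, "EX_acetate_e", lower = -2, upper = 0)
  m <- set_bounds(m, "Biomass", upper = 0)
  m <- set_bounds(m, "ETOX", upper = 0)       # isolate the elongation lump
  sol <- solve_fba(m, "EX_butyrate_e")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$fluxes[["EX_ethanol_e"]], sol$fluxes[["EX_acetate_e"]],
               tolerance = 1e-8)
  expect_equal(sol$fluxes[["EX_butyrate_e"]], -sol$fluxes[["EX_ethanol_e"]],
               tolerance = 1e-8)
})

test_that("odd chains are unreachable without propionate", {
  m <- make_toy_chain_elongator()
  m <- set_bounds(m, "EX_ethanol_e", lower = -10)
  m <- set_bounds(m, "EX_acetate_e", lower = -10)
  # propionate exchange stays export-only: no odd-chain precursor
  for (target in c("EX_valerate_e", "EX_heptanoate_e")) {
    sol <- solve_fba(m, target)
    expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  }
  # opening propionate makes valerate reachable
  m2 <- set_bounds(m, "EX_propionate_e", lower = -5)
  expect_gt(solve_fba(m2, "EX_valerate_e")$objective_value, 0.1)
})

test_that("generators are deterministic given a config", {
  a <- make_toy_triculture()
  b <- make_toy_triculture()
  expect_identical(a$reactions, b$reactions)
  expect_identical(as.matrix(a$S), as.matrix(b$S))
})

test_that("chemostat simulator recovers configured rates", {
  # exact at zero noise
  rec <- simulate_chemostat_observations(c(acetate = 0.51), 1 / 48, 0.4,
                                         noise_sd = 0, seed = 1)[[1]]
  expect_equal(rec$concentrations[["acetate"]], 0.51 / ((1 / 48) * 0.4))
  expect_equal(steady_state_rate(rec, "acetate"), 0.51, tolerance = 1e-12)
  # noisy series: mean recovered rate within 3 standard errors
  n <- 20
  recs <- simulate_chemostat_observations(c(acetate = 0.51), 1 / 48, 0.4,
                                          noise_sd = 0.05, seed = 42, n = n)
  rates <- vapply(recs, steady_state_rate, numeric(1), compound = "acetate")
  se <- sd(rates) / sqrt(n)
  expect_lt(abs(mean(rates) - 0.51), 3 * se + 1e-12)
  # determinism
  recs2 <- simulate_chemostat_observations(c(acetate = 0.51), 1 / 48, 0.4,
                                           noise_sd = 0.05, seed = 42, n = n)
  expect_identical(recs, recs2)
})
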
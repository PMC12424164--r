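# Chemostat mass-balance and physico-chemical calculators.

test_that("dilution rate conversions match chemostat arithmetic", {
  expect_equal(round(dilution_rate(48), 3), 0.021)
  expect_equal(dilution_rate(1), 1)
  expect_equal(dilution_rate(20), 0.05)
  expect_equal(hrt_from_dilution(dilution_rate(48)), 48)
  expect_error(dilution_rate(0), "positive")
  expect_error(hrt_from_dilution(-1), "positive")
})

test_that("gas flow converts by the ideal gas law at the stated conditions", {
  # 4 mL/min of 70% CO at 0 C, 101.325 kPa
  expect_equal(gas_flow_to_molar(4, 0.70, 0, 101.325), 7.50, tolerance = 0.01)
  expect_equal(gas_flow_to_molar(4, 0.70, 25, 101.325), 6.87, tolerance = 0.01)
  expect_equal(gas_flow_to_molar(4, 0, 0, 101.325), 0)
  expect_error(gas_flow_to_molar(4, 0.7, -300, 101.325), "absolute zero")
  expect_error(gas_flow_to_molar(4, 1.2, 0, 101.325), "fraction")
})

test_that("consumption percentage is a guarded ratio", {
  expect_equal(consumption_percent(3.5, 7.5), 46.7, tolerance = 0.05)
  expect_equal(consumption_percent(0, 7.5), 0)
  expect_equal(consumption_percent(7.5, 7.5), 100)
  expect_error(consumption_percent(1, 0), "positive")
})

test_that("Henderson-Hasselbalch fraction behaves across the pH range", {
  expect_equal(undissociated_fraction(4.83, 4.83), 0.5)
  expect_equal(undissociated_fraction(7, 4.83), 0.00672, tolerance = 1e-3)
  expect_equal(undissociated_concentration(42.8, 7, 4.83), 0.287,
               tolerance = 1e-2)
  # limits and monotonicity
  expect_gt(undissociated_fraction(0, 4.83), 0.999)
  ph <- seq(3, 10, by = 0.25)
  fr <- undissociated_fraction(ph, 4.83)
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr[ph > 4.83] < 0.5 & fr[ph > 4.83] > 0))
})

test_that("degree of reduction follows 4C + H - 2O (- 3N)", {
  expect_equal(degree_of_reduction("C2H4O2"), 8)    # acetate
  expect_equal(degree_of_reduction("CO"), 2)
  expect_equal(degree_of_reduction("H2"), 2)
  expect_equal(degree_of_reduction("CO2"), 0)
  expect_equal(degree_of_reduction("H2O"), 0)
  expect_equal(degree_of_reduction("NH3"), 0)       # N reference state
  expect_error(degree_of_reduction("NaCl"), "reference state")
})

test_that("balance recovery closes on hand-balanced chain elongation", {
  # 6 ethanol + 4 acetate -> 5 butyrate + 2 H2 (+ water):
  # carbon 12+8 = 20; electrons 72+32 = 100+4
  inputs <- c(ethanol = 6, acetate = 4)
  outputs <- c(butyrate = 5, h2 = 2)
  expect_equal(balance_recovery(inputs, outputs, "carbon"), 100)
  expect_equal(balance_recovery(inputs, outputs, "electrons"), 100)
  expect_equal(balance_recovery(inputs, inputs, "carbon"), 100)
  expect_equal(balance_recovery(c(acetate = 2), c(acetate = 1), "carbon"), 50)
  expect_error(balance_recovery(c(mystery = 1), c(acetate = 1), "carbon"),
               "mystery")
  # scale invariance
  expect_equal(balance_recovery(inputs * 7, outputs * 7, "electrons"),
               balance_recovery(inputs, outputs, "electrons"))
})

test_that("degree of reduction is additive over balanced reactions", {
  m <- make_toy_propionigen()
  st <- reaction_stoichiometry(m, "ACR")
  g <- vapply(names(st), function(mid) {
    degree_of_reduction(m$metabolites$formula[m$metabolites$id == mid])
  }, numeric(1))
  expect_equal(sum(g * st), 0)
  # the acrylate lump by hand: 3 ethanol (36) + 2 CO2 (0) vs
  # 2 propionate (28) + acetate (8)
  expect_equal(3 * degree_of_reduction("C2H6O"), 36)
  expect_equal(2 * degree_of_reduction("C3H6O2") + degree_of_reduction("C2H4O2"),
               36)
})

test_that("steady-state rates follow D * V * (c_out - c_in) plus gas terms", {
  rec <- chemostat_record(0.4, 1 / 48, c(acetate = 63.2))
  expect_equal(steady_state_rate(rec, "acetate"), 0.527, tolerance = 1e-3)
  rec2 <- chemostat_record(0.4, 1 / 48, c(acetate = 10),
                           inflow_concentrations = c(acetate = 10))
  expect_equal(steady_state_rate(rec2, "acetate"), 0)
  rec3 <- chemostat_record(0.4, 1 / 48, c(acetate = 0),
                           gas_in = c(co = 7.5), gas_out = c(co = 4))
  expect_equal(steady_state_rate(rec3, "co"), -3.5)
  expect_error(steady_state_rate(rec, "butyrate"), "not in record")
})
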
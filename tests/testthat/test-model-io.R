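# Model containers, equation parsing, SBML / tabular round trips, and the
# elemental balance checker.

test_that("formula parsing and formatting round-trip", {
  expect_equal(parse_formula("C2H4O2"), c(C = 2, H = 4, O = 2))
  expect_equal(parse_formula("CO2"), c(C = 1, O = 2))
  expect_equal(parse_formula("C10H18O5N2"),
               c(C = 10, H = 18, O = 5, N = 2))
  expect_length(parse_formula(""), 0)
  expect_null(parse_formula(NA_character_))
  expect_error(parse_formula("C2@H4"), "cannot parse")
  expect_equal(format_formula(parse_formula("C2H4O2")), "C2H4O2")
  expect_equal(molar_mass("H2O"), 2 * 1.008 + 15.999, tolerance = 1e-9)
})

test_that("reaction equations parse with signs, coefficients and errors", {
  st <- parse_reaction_equation("1 co_e + 1 h2o_aw -> 1 co2_aw + 2 fdred_aw")
  expect_equal(st, c(co_e = -1, h2o_aw = -1, co2_aw = 1, fdred_aw = 2))
  # exchange: empty product side
  expect_equal(parse_reaction_equation("co_e ->"), c(co_e = -1))
  st2 <- parse_reaction_equation("2 co2_aw + 8 fdred_aw -> accoa_aw")
  expect_equal(st2[c("co2_aw", "fdred_aw")], c(co2_aw = -2, fdred_aw = -8))
  expect_error(parse_reaction_equation("a b c"), "separator")
  expect_error(parse_reaction_equation("->"), "empty")
})

test_that("model invariants are enforced", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_error(
    set_bounds(m, "R1", lower = 5, upper = 1), "lower_bound > upper_bound")
  expect_error(set_bounds(m, "nope", lower = 0), "unknown reaction")
  # unknown metabolite in an equation names the id and the line
  expect_error(model_from_equations(
    id = "bad", compartments = c(c = "c", e = "e"),
    metabolites = data.frame(id = "a_c", compartment = "c"),
    reactions = data.frame(id = "r1", equation = "a_c -> ghost_c",
                           lower_bound = 0, upper_bound = 1),
    objective_id = "r1"), "ghost_c")
})

test_that("exchange detection follows the single-extracellular rule", {
  m <- chain_model()
  expect_equal(m$reactions$id[is_exchange(m)], c("EX_a_e", "EX_b_e"))
  # override by explicit list
  expect_equal(sum(is_exchange(m, exchange_ids = "T_a")), 1)
})

test_that("SBML round trip preserves all carried fields", {
  for (make in list(make_toy_acetogen, make_toy_propionigen,
                    make_toy_chain_elongator)) {
    m <- make()
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_true(syncomfba:::model_equal(m, m2))
    expect_equal(sort(m2$reactions$id[is_exchange(m2)]),
                 sort(m$reactions$id[is_exchange(m)]))
  }
})

test_that("SBML reader errors name the offending reaction", {
  m <- chain_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  txt <- readLines(path)
  txt <- sub(' fbc:lowerFluxBound="[^"]*"', "", txt[])
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, path2)
  expect_error(read_sbml(path2), "missing a flux bound")
  expect_error(read_sbml(textConnection("<not-xml")), class = "error")
})

test_that("metabolites without formulas survive the SBML round trip", {
  m <- make_toy_acetogen()
  m$metabolites$formula[m$metabolites$id == "co_c"] <- NA_character_
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_true(is.na(m2$metabolites$formula[m2$metabolites$id == "co_c"]))
  expect_true(syncomfba:::model_equal(m, m2))
})

test_that("writers refuse empty models", {
  m <- chain_model()
  empty <- m
  empty$reactions <- m$reactions[0, ]
  empty$S <- m$S[, 0, drop = FALSE]
  empty$objective_id <- NA_character_
  empty$biomass_id <- NA_character_
  expect_error(write_sbml(empty, tempfile()), "no reactions")
  expect_error(write_tabular(empty, tempfile()), "no reactions")
})

test_that("tabular dialects round-trip toy and community models", {
  tri <- make_toy_triculture()
  for (ext in c(".json", "")) {
    path <- file.path(withr::local_tempdir(), paste0("model", ext))
    write_tabular(tri, path)
    tri2 <- read_tabular(path)
    expect_true(syncomfba:::model_equal(tri, tri2))
  }
})

test_that("elemental balance flags exactly the imbalanced reactions", {
  # hand counts on a tiny fixture: co -> co2 misses one O
  m <- model_from_equations(
    id = "imb", compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("co_c", "co2_c", "h2o_c", "o2_c", "x_c"),
      formula = c("CO", "CO2", "H2O", "O2", NA), charge = 0L,
      compartment = "c"),
    reactions = data.frame(
      id = c("BAD", "GOOD", "UNK"),
      equation = c("co_c -> co2_c", "2 co_c + o2_c -> 2 co2_c",
                   "x_c -> co_c"),
      lower_bound = 0, upper_bound = 1),
    objective_id = "GOOD", biomass_id = NA_character_)
  rep <- check_elemental_balance(m)
  expect_equal(rep$status[rep$reaction_id == "BAD"], "imbalanced")
  expect_match(rep$imbalance[rep$reaction_id == "BAD"], "O:\\+1")
  expect_equal(rep$status[rep$reaction_id == "GOOD"], "balanced")
  expect_equal(rep$status[rep$reaction_id == "UNK"], "unchecked")
})

test_that("empty model yields an empty balance report", {
  m <- chain_model()
  m$reactions <- m$reactions[0, ]
  m$S <- m$S[, 0, drop = FALSE]
  m$objective_id <- NA_character_
  m$biomass_id <- NA_character_
  expect_equal(nrow(check_elemental_balance(m)), 0)
})
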
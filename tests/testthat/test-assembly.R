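# Species tagging, merging over the shared extracellular pool, community
# biomass parametrization, and chemostat condition application.

test_that("tagging suffixes intracellular ids and spares extracellular", {
  aw <- make_toy_acetogen()
  t1 <- tag_species(aw, "aw")
  expect_true("acetate_c_aw" %in% t1$metabolites$id)
  expect_true("co_e" %in% t1$metabolites$id)          # untouched
  expect_true("EX_co_e" %in% t1$reactions$id)         # exchange untouched
  expect_true("CODH_aw" %in% t1$reactions$id)
  expect_equal(t1$biomass_id, "Biomass_aw")
  expect_error(tag_species(t1, "aw"), "collides")
  expect_true(syncomfba:::model_equal(untag_species(t1, "aw"), aw))
})

test_that("merging unifies shared extracellular reactions with union bounds", {
  p <- mini_producer()
  q <- mini_consumer()
  cm <- merge_models(list(species_spec(p, "p", 0.6),
                          species_spec(q, "q", 0.4)), id = "duo")
  # shared metabolite m_e appears once, one exchange, two transports
  expect_equal(sum(cm$metabolites$id == "m_e"), 1)
  expect_equal(sum(cm$reactions$id == "EX_m_e"), 1)
  expect_true(all(c("T_m_p", "T_m_q") %in% cm$reactions$id))
  # producer had EX_m_e [0,1000], consumer [0,1000]: union is unchanged;
  # EX_s_e only in producer keeps its bounds
  ex <- cm$reactions[cm$reactions$id == "EX_s_e", ]
  expect_equal(ex$lower_bound, -5)
  # disjoint extracellular sets union up
  expect_setequal(
    cm$metabolites$id[cm$metabolites$compartment == "e"],
    c("s_e", "m_e", "p_e"))
})

test_that("conflicting formulas for a shared metabolite are rejected", {
  p <- mini_producer()
  q <- mini_consumer()
  q$metabolites$formula[q$metabolites$id == "m_e"] <- "C3"
  expect_error(
    merge_models(list(species_spec(p, "p", 0.5), species_spec(q, "q", 0.5))),
    "m_e")
})

test_that("community biomass consumes fractions of species biomass", {
  tri <- make_toy_triculture(fractions = c(aw = 0.5, an = 0.3, ck = 0.2))
  st <- reaction_stoichiometry(tri, "EX_Biomass_e")
  u <- 1000 / molar_mass("C10H18O5N2")   # biomass units per gram
  expect_equal(st[["biomass_c_aw"]], -0.5 * u, tolerance = 1e-9)
  expect_equal(st[["biomass_c_an"]], -0.3 * u, tolerance = 1e-9)
  expect_equal(st[["biomass_c_ck"]], -0.2 * u, tolerance = 1e-9)
  # re-parametrization without rebuilding
  tri2 <- add_community_biomass(tri, c(aw = 0.7, an = 0.1, ck = 0.2))
  st2 <- reaction_stoichiometry(tri2, "EX_Biomass_e")
  expect_equal(st2[["biomass_c_aw"]], -0.7 * u, tolerance = 1e-9)
  expect_error(add_community_biomass(tri, c(aw = 0.5, an = 0.3, ck = 0.3)),
               "sum")
})

test_that("condition application fixes species biomass to fraction*X*mu", {
  tri <- make_toy_triculture()
  cond <- paper_condition()
  con <- apply_condition(tri, cond)
  rx <- con$reactions
  expect_equal(rx$lower_bound[rx$id == "Biomass_aw"], 0.5 * 0.32 * 0.02)
  expect_equal(rx$upper_bound[rx$id == "Biomass_aw"], 0.0032)
  expect_equal(rx$lower_bound[rx$id == "Biomass_an"], 0.00192)
  expect_equal(rx$lower_bound[rx$id == "Biomass_ck"], 0.00128)
  expect_equal(rx$lower_bound[rx$id == "EX_Biomass_e"], 0.0064)
  # exchange override lands verbatim
  expect_equal(rx$lower_bound[rx$id == "EX_co_e"], -3.5)
  expect_equal(rx$upper_bound[rx$id == "EX_co_e"], -1)
  # finite specific bounds scaled by X * fraction; sentinels untouched
  expect_equal(rx$upper_bound[rx$id == "T_co_aw"], 20 * 0.32 * 0.5)
  expect_equal(rx$upper_bound[rx$id == "CODH_aw"], 1000)
  # original untouched
  expect_equal(tri$reactions$upper_bound[tri$reactions$id == "T_co_aw"], 20)
})

test_that("condition application is pure (idempotent under the same condition)", {
  tri <- make_toy_triculture()
  cond <- paper_condition()
  once <- apply_condition(tri, cond)
  twice <- apply_condition(once, cond)
  expect_equal(twice$reactions, once$reactions)
  expect_true(syncomfba:::model_equal(once, twice))
})

test_that("condition validation rejects bad scenarios", {
  expect_error(community_condition(-0.1, 0.32, c(aw = 1)), "growth_rate")
  expect_error(community_condition(0.02, 0, c(aw = 1)), "total_biomass")
  expect_error(community_condition(0.02, 0.32, numeric(0)), "nonempty")
  expect_error(community_condition(0.02, 0.32, c(aw = 0.6, an = 0.6)), "sum")
  expect_error(
    community_condition(0.02, 0.32, c(aw = 1),
                        exchange_bounds = list(EX_co_e = c(1, -1))),
    "lower <= upper")
})

test_that("steady state closes the extracellular bookkeeping", {
  tri <- make_toy_triculture()
  con <- apply_condition(tri, paper_condition())
  sol <- solve_fba(con)
  expect_equal(sol$status, "optimal")
  # for each shared metabolite: transports + exchange sum to zero
  for (met in c("ethanol_e", "acetate_e", "co2_e", "propionate_e")) {
    row <- con$S[met, ]
    expect_lt(abs(sum(row * sol$fluxes)), 1e-6)
  }
})

test_that("scaling biomass and exchange bounds scales the optimum (homogeneity)", {
  tri <- make_toy_triculture()
  base <- community_condition(0.02, 0.32, c(aw = 0.5, an = 0.3, ck = 0.2),
                              list(EX_co_e = c(-3.5, -1)))
  dbl <- community_condition(0.02, 0.64, c(aw = 0.5, an = 0.3, ck = 0.2),
                             list(EX_co_e = c(-7, -2)))
  s1 <- solve_fba(apply_condition(tri, base))
  s2 <- solve_fba(apply_condition(tri, dbl))
  expect_equal(s2$objective_value, 2 * s1$objective_value, tolerance = 1e-6)
  # a representative product optimum doubles as well
  m1 <- apply_condition(tri, base)
  m2 <- apply_condition(tri, dbl)
  f1 <- solve_fba(m1, "EX_acetate_e")$objective_value
  f2 <- solve_fba(m2, "EX_acetate_e")$objective_value
  expect_equal(f2, 2 * f1, tolerance = 1e-6)
})
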
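# Toy three-species syngas community: a CO/H2 acetogen (Wood-Ljungdahl),
# an ethanol+CO2 propionigen (acrylate route), and an ethanol-driven chain
# elongator (reverse beta-oxidation, even and odd chains). Small, lumped,
# and elementally balanced, so the whole cFBA pipeline is testable without
# downloading genome-scale models.
#
# Conventions: electron carriers are collapsed into one reduced-equivalent
# pool "red" (2 e-, elementally H2); ATP is an element-free token whose
# yields sit inside the catabolic lumps (a free-standing [H]->ATP reaction
# would close a perpetual ATP cycle with the hydrogenase). Biomass reaction
# flux is in g CDW h^-1: one flux unit makes 1 g of the biomass
# pseudo-metabolite (formula CH1.8O0.5N0.2, scaled x10 to integer counts).

.TOY_FORMULAS <- c(
  co = "CO", co2 = "CO2", h2 = "H2", h2o = "H2O", nh3 = "NH3", red = "H2",
  atp = "", acetyl = "C2H4O2", acetate = "C2H4O2", ethanol = "C2H6O",
  propionate = "C3H6O2", propanol = "C3H8O",
  butyrate = "C4H8O2", butanol = "C4H10O",
  valerate = "C5H10O2", pentanol = "C5H12O",
  caproate = "C6H12O2", hexanol = "C6H14O",
  heptanoate = "C7H14O2")

#' Toy community configuration
#'
#' @param include_reduction_pathways Include the acetogen's carboxylate ->
#'   alcohol reduction lumps (C3-C6)?
#' @param atp_per_acetate ATP yield of the acetate kinase branch (mol/mol).
#' @param atp_per_ethanol ATP yield of the solventogenic branch.
#' @param atp_per_acrylate ATP yield per acrylate-pathway lump (3 ethanol).
#' @param atp_per_oxidation ATP yield of ethanol oxidation to acetate.
#' @param ngam_rate Non-growth-associated maintenance, mmol ATP
#'   gCDW^-1 h^-1 (lower bound on the NGAM reaction).
#' @param gam_per_biomass Growth-associated maintenance, mmol ATP per g
#'   biomass.
#' @param biomass_formula Biomass pseudo-metabolite formula (default
#'   `"C10H18O5N2"`, i.e. CH1.8O0.5N0.2 x 10; molar mass ~246 g/mol, about
#'   24.6 g per C-mol).
#' @param bounds_default Sentinel magnitude for "unbounded" reactions
#'   (default 1000; bounds at or above it are never scaled by biomass).
#' @param uptake_vmax_co Transport capacity for CO uptake, mmol gCDW^-1
#'   h^-1. The default (20) makes CO processing scale with acetogen biomass
#'   and limit the community at low acetogen fractions, the mechanism that
#'   shapes the chemostat feasibility boundary.
#' @param uptake_vmax_h2 Transport capacity for H2 uptake, mmol gCDW^-1
#'   h^-1 (default 30, ample for the H2 co-feeding scans).
#' @param uptake_vmax_organics Transport capacity for organic substrate
#'   uptake, mmol gCDW^-1 h^-1.
#' @return A `toy_config` list.
#' @export
toy_config <- function(include_reduction_pathways = TRUE,
                       atp_per_acetate = 1, atp_per_ethanol = 0.5,
                       atp_per_acrylate = 1, atp_per_oxidation = 1,
                       ngam_rate = 0.3, gam_per_biomass = 40,
                       biomass_formula = "C10H18O5N2",
                       bounds_default = 1000,
                       uptake_vmax_co = 20, uptake_vmax_h2 = 30,
                       uptake_vmax_organics = 10) {
  stopifnot(atp_per_acetate >= 0, ngam_rate >= 0, gam_per_biomass >= 0,
            bounds_default > 0)
  bf <- parse_formula(biomass_formula)
  if (is.null(bf) || !"C" %in% names(bf) || bf[["C"]] < 1) {
    stop("biomass formula must contain at least one carbon")
  }
  structure(list(
    include_reduction_pathways = include_reduction_pathways,
    atp_per_acetate = atp_per_acetate, atp_per_ethanol = atp_per_ethanol,
    atp_per_acrylate = atp_per_acrylate,
    atp_per_oxidation = atp_per_oxidation,
    ngam_rate = ngam_rate, gam_per_biomass = gam_per_biomass,
    biomass_formula = biomass_formula, bounds_default = bounds_default,
    uptake_vmax_co = uptake_vmax_co, uptake_vmax_h2 = uptake_vmax_h2,
    uptake_vmax_organics = uptake_vmax_organics), class = "toy_config")
}

# per-gram biomass unit count (mmol of the pseudo-metabolite per g CDW)
.biomass_units_per_g <- function(cfg) 1000 / molar_mass(cfg$biomass_formula)

.toy_metabolites <- function(cyt_ids, ext_ids, cfg) {
  mk <- function(ids, comp) {
    data.frame(id = paste0(ids, "_", comp), name = ids,
               formula = unname(c(.TOY_FORMULAS, biomass = cfg$biomass_formula)[ids]),
               charge = 0L, compartment = comp, stringsAsFactors = FALSE)
  }
  rbind(mk(cyt_ids, "c"), mk(ext_ids, "e"))
}

.toy_model <- function(id, cyt_ids, ext_ids, rxn, cfg, biomass_id,
                       ngam_id = "NGAM") {
  model_from_equations(
    id = id, compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = .toy_metabolites(cyt_ids, ext_ids, cfg),
    reactions = rxn, objective_id = biomass_id, biomass_id = biomass_id,
    ngam_id = ngam_id, extracellular_id = "e")
}

.rx <- function(id, equation, lb, ub, name = id) {
  data.frame(id = id, name = name, equation = equation,
             lower_bound = lb, upper_bound = ub, stringsAsFactors = FALSE)
}

# biomass synthesis equation from a C2 precursor (acetyl or ethanol route)
.biomass_equation <- function(cfg, precursor) {
  u <- .biomass_units_per_g(cfg)
  num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  if (precursor == "acetyl") {
    # 5 C2H4O2 + 2 NH3 + H2 -> C10H18O5N2 + 5 H2O   (per biomass unit)
    sprintf("%s acetyl_c + %s nh3_c + %s red_c + %s atp_c -> %s biomass_c + %s h2o_c",
            num(5 * u), num(2 * u), num(u), num(cfg$gam_per_biomass),
            num(u), num(5 * u))
  } else {
    # 5 C2H6O + 2 NH3 -> C10H18O5N2 + 9 H2          (per biomass unit)
    sprintf("%s ethanol_c + %s nh3_c + %s atp_c -> %s biomass_c + %s h2_c",
            num(5 * u), num(2 * u), num(cfg$gam_per_biomass),
            num(u), num(9 * u))
  }
}

#' Toy acetogen (Wood-Ljungdahl pathway on CO/H2)
#'
#' Lumped reactions: CO dehydrogenase (CO + H2O -> CO2 + \[H\]),
#' hydrogenase (H2 -> \[H\]), Wood-Ljungdahl lump (2 CO2 + 4 \[H\] ->
#' acetyl unit), acetate kinase branch (acetyl -> acetate + ATP),
#' solventogenic branch (acetyl + 2 \[H\] -> ethanol + H2O), optional
#' carboxylate-to-alcohol reductions (acid + 2 \[H\] -> alcohol + H2O,
#' C3-C6), NGAM, and biomass synthesis. `\[H\]` is a 2-electron reduced
#' carrier. All internal reactions are elementally balanced.
#'
#' @param cfg A [toy_config()].
#' @return A `metabolic_model`.
#' @export
make_toy_acetogen <- function(cfg = toy_config()) {
  B <- cfg$bounds_default
  vo <- cfg$uptake_vmax_organics
  num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  rxn <- rbind(
    .rx("EX_co_e", "co_e ->", -vo, B),
    .rx("EX_h2_e", "h2_e ->", 0, B),
    .rx("EX_co2_e", "co2_e ->", 0, B),
    .rx("EX_acetate_e", "acetate_e ->", 0, B),
    .rx("EX_ethanol_e", "ethanol_e ->", 0, B),
    .rx("EX_h2o_e", "h2o_e ->", -B, B),
    .rx("EX_nh3_e", "nh3_e ->", -B, B),
    .rx("T_co", "co_e -> co_c", 0, cfg$uptake_vmax_co),
    .rx("T_h2", "h2_e -> h2_c", 0, cfg$uptake_vmax_h2),
    .rx("T_co2", "co2_c -> co2_e", -B, B),
    .rx("T_acetate", "acetate_c -> acetate_e", 0, B),
    .rx("T_ethanol", "ethanol_c -> ethanol_e", 0, B),
    .rx("T_h2o", "h2o_e -> h2o_c", -B, B),
    .rx("T_nh3", "nh3_e -> nh3_c", 0, vo),
    .rx("CODH", "co_c + h2o_c -> co2_c + red_c", 0, B),
    .rx("HYD", "h2_c -> red_c", 0, B),
    .rx("WLP", "2 co2_c + 4 red_c -> acetyl_c + 2 h2o_c", 0, B),
    .rx("ACK", sprintf("acetyl_c -> acetate_c + %s atp_c",
                       num(cfg$atp_per_acetate)), 0, B),
    .rx("ETOH", sprintf("acetyl_c + 2 red_c -> ethanol_c + h2o_c + %s atp_c",
                        num(cfg$atp_per_ethanol)), 0, B),
    .rx("NGAM", "atp_c ->", cfg$ngam_rate, B),
    .rx("Biomass", .biomass_equation(cfg, "acetyl"), 0, B),
    .rx("DM_biomass", "biomass_c ->", 0, B))
  cyt <- c("co", "h2", "co2", "h2o", "nh3", "red", "atp", "acetyl",
           "acetate", "ethanol", "biomass")
  ext <- c("co", "h2", "co2", "acetate", "ethanol", "h2o", "nh3")
  if (cfg$include_reduction_pathways) {
    acids <- c(propionate = "propanol", butyrate = "butanol",
               valerate = "pentanol", caproate = "hexanol")
    for (acid in names(acids)) {
      alcohol <- acids[[acid]]
      rxn <- rbind(
        rxn,
        .rx(paste0("EX_", acid, "_e"), paste0(acid, "_e ->"), 0, B),
        .rx(paste0("EX_", alcohol, "_e"), paste0(alcohol, "_e ->"), 0, B),
        .rx(paste0("T_", acid), paste0(acid, "_e -> ", acid, "_c"), 0, vo),
        .rx(paste0("T_", alcohol), paste0(alcohol, "_c -> ", alcohol, "_e"),
            0, B),
        .rx(paste0("RED_", acid),
            paste0(acid, "_c + 2 red_c -> ", alcohol, "_c + h2o_c"), 0, B))
      cyt <- c(cyt, acid, alcohol)
      ext <- c(ext, acid, alcohol)
    }
  }
  # ETOH branch adds atp only when the yield is nonzero; drop the 0-term
  if (cfg$atp_per_ethanol == 0) {
    rxn$equation[rxn$id == "ETOH"] <-
      "acetyl_c + 2 red_c -> ethanol_c + h2o_c"
  }
  if (cfg$atp_per_acetate == 0) {
    rxn$equation[rxn$id == "ACK"] <- "acetyl_c -> acetate_c"
  }
  .toy_model("toy_acetogen", cyt, ext, rxn, cfg, "Biomass")
}

#' Toy propionigen (acrylate pathway on ethanol + CO2)
#'
#' Lumped reactions: ethanol uptake, acrylate-pathway lump
#' (3 ethanol + 2 CO2 -> 2 propionate + acetate + H2O), ethanol oxidation
#' (ethanol + H2O -> acetate + 2 H2), NGAM and biomass. The
#' propionate:acetate ratio is 2:1 on the pure acrylate route and tunable
#' downward by mixing in oxidation flux.
#'
#' @param cfg A [toy_config()].
#' @return A `metabolic_model`.
#' @export
make_toy_propionigen <- function(cfg = toy_config()) {
  B <- cfg$bounds_default
  vo <- cfg$uptake_vmax_organics
  num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  acr <- sprintf(
    "3 ethanol_c + 2 co2_c -> 2 propionate_c + acetate_c + h2o_c + %s atp_c",
    num(cfg$atp_per_acrylate))
  if (cfg$atp_per_acrylate == 0) {
    acr <- "3 ethanol_c + 2 co2_c -> 2 propionate_c + acetate_c + h2o_c"
  }
  etox <- sprintf("ethanol_c + h2o_c -> acetate_c + 2 h2_c + %s atp_c",
                  num(cfg$atp_per_oxidation))
  if (cfg$atp_per_oxidation == 0) {
    etox <- "ethanol_c + h2o_c -> acetate_c + 2 h2_c"
  }
  # uptake happens via the transport reactions; exchanges default to the
  # CO-only community medium (no free organics) and are opened per scenario
  rxn <- rbind(
    .rx("EX_ethanol_e", "ethanol_e ->", 0, B),
    .rx("EX_co2_e", "co2_e ->", -B, B),
    .rx("EX_propionate_e", "propionate_e ->", 0, B),
    .rx("EX_acetate_e", "acetate_e ->", 0, B),
    .rx("EX_h2_e", "h2_e ->", 0, B),
    .rx("EX_h2o_e", "h2o_e ->", -B, B),
    .rx("EX_nh3_e", "nh3_e ->", -B, B),
    .rx("T_ethanol", "ethanol_e -> ethanol_c", 0, vo),
    .rx("T_co2", "co2_e -> co2_c", -B, B),
    .rx("T_propionate", "propionate_c -> propionate_e", 0, B),
    .rx("T_acetate", "acetate_c -> acetate_e", 0, B),
    .rx("T_h2", "h2_c -> h2_e", 0, B),
    .rx("T_h2o", "h2o_e -> h2o_c", -B, B),
    .rx("T_nh3", "nh3_e -> nh3_c", 0, vo),
    .rx("ACR", acr, 0, B), .rx("ETOX", etox, 0, B),
    .rx("NGAM", "atp_c ->", cfg$ngam_rate, B),
    .rx("Biomass", .biomass_equation(cfg, "ethanol"), 0, B),
    .rx("DM_biomass", "biomass_c ->", 0, B))
  cyt <- c("ethanol", "co2", "propionate", "acetate", "h2", "h2o", "nh3",
           "atp", "biomass")
  ext <- c("ethanol", "co2", "propionate", "acetate", "h2", "h2o", "nh3")
  .toy_model("toy_propionigen", cyt, ext, rxn, cfg, "Biomass")
}

#' Toy chain elongator (reverse beta-oxidation on ethanol)
#'
#' Lumped two-carbon elongation cycles: ethanol + acetate -> butyrate,
#' ethanol + butyrate -> caproate, ethanol + propionate -> valerate,
#' ethanol + valerate -> heptanoate (each + H2O), plus ethanol oxidation
#' with H2 evolution, NGAM, and biomass. Odd-chain products (valerate,
#' heptanoate) are reachable only when propionate is available.
#'
#' @param cfg A [toy_config()].
#' @return A `metabolic_model`.
#' @export
make_toy_chain_elongator <- function(cfg = toy_config()) {
  B <- cfg$bounds_default
  vo <- cfg$uptake_vmax_organics
  num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  etox <- sprintf("ethanol_c + h2o_c -> acetate_c + 2 h2_c + %s atp_c",
                  num(cfg$atp_per_oxidation))
  if (cfg$atp_per_oxidation == 0) {
    etox <- "ethanol_c + h2o_c -> acetate_c + 2 h2_c"
  }
  rxn <- rbind(
    .rx("EX_ethanol_e", "ethanol_e ->", 0, B),
    .rx("EX_acetate_e", "acetate_e ->", 0, B),
    .rx("EX_propionate_e", "propionate_e ->", 0, B),
    .rx("EX_butyrate_e", "butyrate_e ->", 0, B),
    .rx("EX_valerate_e", "valerate_e ->", 0, B),
    .rx("EX_caproate_e", "caproate_e ->", 0, B),
    .rx("EX_heptanoate_e", "heptanoate_e ->", 0, B),
    .rx("EX_h2_e", "h2_e ->", 0, B),
    .rx("EX_h2o_e", "h2o_e ->", -B, B),
    .rx("EX_nh3_e", "nh3_e ->", -B, B),
    .rx("T_ethanol", "ethanol_e -> ethanol_c", 0, vo),
    .rx("T_acetate", "acetate_e -> acetate_c", 0, vo),
    .rx("T_propionate", "propionate_e -> propionate_c", 0, vo),
    .rx("T_butyrate", "butyrate_c -> butyrate_e", -vo, B),
    .rx("T_valerate", "valerate_c -> valerate_e", -vo, B),
    .rx("T_caproate", "caproate_c -> caproate_e", 0, B),
    .rx("T_heptanoate", "heptanoate_c -> heptanoate_e", 0, B),
    .rx("T_h2", "h2_c -> h2_e", 0, B),
    .rx("T_h2o", "h2o_e -> h2o_c", -B, B),
    .rx("T_nh3", "nh3_e -> nh3_c", 0, vo),
    .rx("ELONG_C4", "ethanol_c + acetate_c -> butyrate_c + h2o_c", 0, B),
    .rx("ELONG_C6", "ethanol_c + butyrate_c -> caproate_c + h2o_c", 0, B),
    .rx("ELONG_C5", "ethanol_c + propionate_c -> valerate_c + h2o_c", 0, B),
    .rx("ELONG_C7", "ethanol_c + valerate_c -> heptanoate_c + h2o_c", 0, B),
    .rx("ETOX", etox, 0, B),
    .rx("NGAM", "atp_c ->", cfg$ngam_rate, B),
    .rx("Biomass", .biomass_equation(cfg, "ethanol"), 0, B),
    .rx("DM_biomass", "biomass_c ->", 0, B))
  cyt <- c("ethanol", "acetate", "propionate", "butyrate", "valerate",
           "caproate", "heptanoate", "h2", "h2o", "nh3", "atp", "biomass")
  ext <- c("ethanol", "acetate", "propionate", "butyrate", "valerate",
           "caproate", "heptanoate", "h2", "h2o", "nh3")
  .toy_model("toy_chain_elongator", cyt, ext, rxn, cfg, "Biomass")
}

#' Toy triculture community model
#'
#' Tags the three toy species (`aw` = acetogen, `an` = propionigen,
#' `ck` = chain elongator), merges them over the shared extracellular pool
#' and installs the ratio-parametrized community biomass reaction.
#'
#' @param cfg A [toy_config()].
#' @param fractions Named fractions `c(aw = , an = , ck = )` summing to 1.
#' @return A `community_model`.
#' @export
make_toy_triculture <- function(cfg = toy_config(),
                                fractions = c(aw = 0.5, an = 0.3, ck = 0.2)) {
  merge_models(list(
    species_spec(make_toy_acetogen(cfg), "aw", fractions[["aw"]]),
    species_spec(make_toy_propionigen(cfg), "an", fractions[["an"]]),
    species_spec(make_toy_chain_elongator(cfg), "ck", fractions[["ck"]])),
    id = "toy_triculture")
}

#' Simulate noisy chemostat steady-state observations
#'
#' Generates a series of chemostat records whose outflow concentrations
#' follow `c = rate / (D * V)` perturbed by multiplicative Gaussian noise —
#' the fixture generator for the mass-balance calculators.
#'
#' @param true_rates Named vector of production rates (mmol h^-1).
#' @param dilution_rate D (h^-1), positive.
#' @param volume Working volume V (L), positive.
#' @param noise_sd Relative (multiplicative) standard deviation, >= 0.
#' @param seed Integer RNG seed.
#' @param n Number of records in the series.
#' @return List of [chemostat_record()] objects.
#' @export
simulate_chemostat_observations <- function(true_rates, dilution_rate,
                                            volume, noise_sd = 0.05,
                                            seed = 1, n = 1) {
  stopifnot(dilution_rate > 0, volume > 0, noise_sd >= 0)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    conc <- true_rates / (dilution_rate * volume)
    noisy <- conc * (1 + stats::rnorm(length(conc), 0, noise_sd))
    chemostat_record(volume = volume, dilution_rate = dilution_rate,
                     concentrations = pmax(noisy, 0))
  })
}
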
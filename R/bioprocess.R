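# Chemostat mass-balance and physico-chemical calculators: dilution rates,
# ideal-gas flow conversion, consumption percentages, steady-state rates,
# Henderson-Hasselbalch undissociated-acid fractions, and carbon /
# degree-of-reduction balances.

.R_GAS <- 8.31446261815324  # J mol^-1 K^-1

#' Per-acid pKa values
#'
#' Literature pKa values for the C2-C6 carboxylic acids handled by the
#' pipeline, alongside the average-acid convention (`"average" = 4.83`).
#' @export
ACID_PKA <- c(acetate = 4.76, propionate = 4.87, butyrate = 4.82,
              valerate = 4.84, caproate = 4.88, average = 4.83)

#' Dilution rate from hydraulic retention time (and back)
#'
#' `D = 1 / HRT`; at steady state in a chemostat the dilution rate equals
#' the community growth rate.
#'
#' @param hrt_hours Hydraulic retention time (h), positive.
#' @return Dilution rate (h^-1).
#' @examples
#' dilution_rate(48)  # ~0.021 h^-1
#' @export
dilution_rate <- function(hrt_hours) {
  if (any(hrt_hours <= 0)) stop("HRT must be positive")
  1 / hrt_hours
}

#' @rdname dilution_rate
#' @param dilution Dilution rate (h^-1), positive.
#' @export
hrt_from_dilution <- function(dilution) {
  if (any(dilution <= 0)) stop("dilution rate must be positive")
  1 / dilution
}

#' Convert a gas flow to a molar rate
#'
#' Ideal-gas conversion `n = P V / (R T)` at explicitly supplied
#' temperature and pressure — there is no hidden STP default, since
#' reported consumption percentages depend on the convention.
#'
#' @param flow_ml_min Total gas flow (mL min^-1), positive.
#' @param fraction Mole (volume) fraction of the gas of interest, in
#'   `[0, 1]`.
#' @param temperature_C Temperature of the stated flow (deg C).
#' @param pressure_kPa Pressure of the stated flow (kPa).
#' @return Molar rate (mmol h^-1).
#' @examples
#' gas_flow_to_molar(4, 0.70, 0, 101.325)  # ~7.5 mmol CO h^-1
#' @export
gas_flow_to_molar <- function(flow_ml_min, fraction, temperature_C,
                              pressure_kPa) {
  if (flow_ml_min < 0) stop("flow must be nonnegative")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (temperature_C < -273.15) stop("temperature below absolute zero")
  vol_m3_h <- flow_ml_min * 1e-6 * 60
  mol_h <- pressure_kPa * 1000 * vol_m3_h / (.R_GAS * (temperature_C + 273.15))
  1000 * mol_h * fraction
}

#' Percentage of substrate consumed
#'
#' @param uptake_rate Consumption rate (mmol h^-1, magnitude).
#' @param inflow_rate Supply rate (mmol h^-1), positive.
#' @return Percentage `100 * uptake / inflow`.
#' @export
consumption_percent <- function(uptake_rate, inflow_rate) {
  if (inflow_rate <= 0) stop("inflow rate must be positive")
  100 * abs(uptake_rate) / inflow_rate
}

#' Undissociated fraction of a weak acid (Henderson-Hasselbalch)
#'
#' `fraction = 1 / (1 + 10^(pH - pKa))`; strictly decreasing in pH, 0.5 at
#' `pH = pKa`.
#'
#' @param pH Culture pH.
#' @param pKa Acid dissociation constant (see [ACID_PKA]).
#' @return Fraction in (0, 1).
#' @examples
#' undissociated_fraction(7, 4.83)  # ~0.0067 (0.67%)
#' @export
undissociated_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pH - pKa))
}

#' @rdname undissociated_fraction
#' @param total_mM Total acid concentration (mM), nonnegative.
#' @return Undissociated concentration (mM).
#' @export
undissociated_concentration <- function(total_mM, pH, pKa) {
  if (any(total_mM < 0)) stop("total concentration must be nonnegative")
  total_mM * undissociated_fraction(pH, pKa)
}

#' Degree of reduction of a compound
#'
#' Available electrons per molecule relative to CO2/H2O (and NH3 for
#' nitrogen): `gamma = 4C + H - 2O - 3N` for CHON species. CO2 and H2O have
#' gamma 0 by construction.
#'
#' @param formula Formula string (e.g. `"C2H4O2"`) or named count vector.
#' @param n_reference Electrons credited per nitrogen relative to the
#'   reference state (default -3, i.e. NH3 as reference).
#' @return Degree of reduction (electrons per molecule).
#' @examples
#' degree_of_reduction("C2H4O2")  # acetate: 8
#' @export
degree_of_reduction <- function(formula, n_reference = -3) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(counts)) stop("cannot compute degree of reduction: missing formula")
  weights <- c(C = 4, H = 1, O = -2, N = n_reference)
  unknown <- setdiff(names(counts), names(weights))
  unknown <- unknown[counts[unknown] != 0]
  if (length(unknown)) {
    stop("no reference state for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(weights[names(counts)] * counts, na.rm = TRUE)
}

#' Carbon or electron balance recovery
#'
#' `100 * sum(outputs basis) / sum(inputs basis)` with basis either carbon
#' atoms or degree-of-reduction electrons. Compound formulas are looked up
#' in `formulas`; biomass enters through whatever formula is supplied for
#' it.
#'
#' @param inputs,outputs Named vectors of amounts (mmol).
#' @param basis `"carbon"` or `"electrons"`.
#' @param formulas Named character vector of formulas covering every
#'   compound; defaults to the toy-community compound table.
#' @return Recovery percentage.
#' @examples
#' balance_recovery(c(ethanol = 6, acetate = 4),
#'                  c(butyrate = 5, h2 = 2), "carbon")
#' @export
balance_recovery <- function(inputs, outputs,
                             basis = c("carbon", "electrons"),
                             formulas = .TOY_FORMULAS) {
  basis <- match.arg(basis)
  weight <- function(amounts) {
    if (length(amounts) == 0) return(0)
    miss <- setdiff(names(amounts), names(formulas))
    if (length(miss)) stop("missing formula for compound: ", miss[1])
    w <- vapply(names(amounts), function(cp) {
      counts <- parse_formula(formulas[[cp]])
      if (basis == "carbon") {
        if ("C" %in% names(counts)) counts[["C"]] else 0
      } else {
        degree_of_reduction(counts)
      }
    }, numeric(1))
    sum(w * amounts)
  }
  denom <- weight(inputs)
  if (denom == 0) stop("inputs carry zero ", basis)
  100 * weight(outputs) / denom
}

#' A chemostat steady-state record
#'
#' @param volume Working volume (L), positive.
#' @param dilution_rate D (h^-1), positive.
#' @param concentrations Named vector of outflow concentrations (mM).
#' @param inflow_concentrations Named vector of feed concentrations (mM);
#'   compounds absent default to 0.
#' @param gas_in,gas_out Optional named vectors of gas transfer rates
#'   (mmol h^-1), e.g. from [gas_flow_to_molar()]; added to the liquid
#'   balance as `gas_out - gas_in`.
#' @return A `chemostat_record`.
#' @export
chemostat_record <- function(volume, dilution_rate, concentrations,
                             inflow_concentrations = numeric(0),
                             gas_in = numeric(0), gas_out = numeric(0)) {
  stopifnot(volume > 0, dilution_rate > 0, all(concentrations >= 0))
  structure(list(volume = volume, dilution_rate = dilution_rate,
                 concentrations = concentrations,
                 inflow_concentrations = inflow_concentrations,
                 gas_in = gas_in, gas_out = gas_out),
            class = "chemostat_record")
}

#' Steady-state production rate from a chemostat record
#'
#' `rate = D * V * (c_out - c_in)`, plus gas outflow minus gas inflow when
#' gas terms are recorded for the compound. Positive = production.
#'
#' @param record A [chemostat_record()].
#' @param compound Compound name present in the record.
#' @return Rate (mmol h^-1).
#' @examples
#' r <- chemostat_record(0.4, 1/48, c(acetate = 63.2))
#' steady_state_rate(r, "acetate")  # ~0.53 mmol h^-1
#' @export
steady_state_rate <- function(record, compound) {
  stopifnot(inherits(record, "chemostat_record"))
  known <- unique(c(names(record$concentrations),
                    names(record$gas_in), names(record$gas_out)))
  if (!compound %in% known) stop("compound not in record: ", compound)
  c_out <- if (compound %in% names(record$concentrations))
    record$concentrations[[compound]] else 0
  c_in <- if (compound %in% names(record$inflow_concentrations))
    record$inflow_concentrations[[compound]] else 0
  rate <- record$dilution_rate * record$volume * (c_out - c_in)
  if (compound %in% names(record$gas_out))
    rate <- rate + record$gas_out[[compound]]
  if (compound %in% names(record$gas_in))
    rate <- rate - record$gas_in[[compound]]
  rate
}
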
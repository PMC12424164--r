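# Flux balance analysis on top of the internal bounded simplex.

#' Solve the FBA linear program
#'
#' Maximizes (or minimizes) the objective flux subject to steady state
#' `S v = 0` and the flux bounds. Optimal solutions are revalidated against
#' the constraints at `1e-6` before being returned; a solution failing that
#' check is reported as solver failure, never silently.
#'
#' @param model A `metabolic_model` (typically constrained via
#'   [apply_condition()]).
#' @param objective_id Reaction to optimize (default: the model objective).
#' @param direction `"max"` or `"min"`.
#' @param tol Validation tolerance (default `1e-6`).
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"solver_failure"`), `objective_value`, and `fluxes`
#'   (named vector; `NULL` unless optimal).
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      direction = c("max", "min"), tol = 1e-6) {
  direction <- match.arg(direction)
  if (is.na(objective_id) || !objective_id %in% model$reactions$id) {
    stop("objective reaction not found: ", objective_id)
  }
  obj <- as.numeric(model$reactions$id == objective_id)
  res <- solve_lp(model$S, rep(0, n_metabolites(model)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  obj, maximize = direction == "max")
  if (res$status == "infeasible") {
    return(structure(list(status = "infeasible",
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  if (res$status != "optimal") {
    return(structure(list(status = "solver_failure",
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  v <- res$x
  resid <- max(abs(drop(model$S %*% v)))
  bound_viol <- max(c(0, model$reactions$lower_bound - v,
                      v - model$reactions$upper_bound))
  if (resid > tol || bound_viol > tol) {
    return(structure(list(status = "solver_failure",
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = stats::setNames(v, model$reactions$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective: ", signif(x$objective_value, 6))
  cat("\n")
  invisible(x)
}

#' Is a community condition feasible?
#'
#' @param cm A `community_model`.
#' @param cond A [community_condition()].
#' @return `TRUE`/`FALSE`, or `NA` on solver failure (failure is a distinct
#'   outcome, never reported as infeasible).
#' @export
check_feasibility <- function(cm, cond) {
  constrained <- apply_condition(cm, cond)
  sol <- solve_fba(constrained)
  switch(sol$status, optimal = TRUE, infeasible = FALSE, NA)
}

#' Scan feasibility over a species-ratio x growth-rate grid
#'
#' Runs [check_feasibility()] for every combination of species fractions
#' and growth rate at fixed total biomass and exchange bounds, mirroring a
#' chemostat feasibility analysis (growth rate = dilution rate).
#'
#' @param cm A `community_model`.
#' @param ratio_grid List of named fraction vectors, each summing to 1
#'   (see [ratio_lattice()]).
#' @param mu_grid Ordered numeric vector of growth rates (h^-1).
#' @param total_biomass Total biomass X (g).
#' @param exchange_bounds As in [community_condition()].
#' @return A `feasibility_grid`: tidy `data.frame` with one row per
#'   (ratio, mu) cell, columns for each species fraction, `mu`, `feasible`,
#'   plus a `matrix` attribute (`|ratios| x |mu|`).
#' @export
scan_feasibility <- function(cm, ratio_grid, mu_grid, total_biomass,
                             exchange_bounds = list()) {
  stopifnot(length(ratio_grid) > 0, length(mu_grid) > 0)
  tags <- cm$species$tag
  rows <- list()
  M <- matrix(NA, nrow = length(ratio_grid), ncol = length(mu_grid))
  for (i in seq_along(ratio_grid)) {
    fr <- ratio_grid[[i]]
    for (j in seq_along(mu_grid)) {
      cond <- community_condition(mu_grid[j], total_biomass, fr,
                                  exchange_bounds)
      M[i, j] <- check_feasibility(cm, cond)
      rows[[length(rows) + 1L]] <- data.frame(
        t(fr[tags]), mu = mu_grid[j], feasible = M[i, j])
    }
  }
  out <- do.call(rbind, rows)
  names(out)[seq_along(tags)] <- tags
  attr(out, "matrix") <- M
  attr(out, "mu_grid") <- mu_grid
  class(out) <- c("feasibility_grid", "data.frame")
  out
}

#' Lattice of species-fraction combinations
#'
#' All combinations of fractions on a regular lattice (default step 0.1,
#' minimum fraction one step) that sum to 1 — the panel structure of a
#' ratio-by-growth-rate feasibility figure.
#'
#' @param tags Species tags.
#' @param step Lattice step (default 0.1).
#' @param min_fraction Minimum fraction per species (default `step`).
#' @return List of named fraction vectors.
#' @export
ratio_lattice <- function(tags, step = 0.1, min_fraction = step) {
  k <- length(tags)
  units <- round(1 / step)
  lo <- round(min_fraction / step)
  grid <- expand.grid(rep(list(seq(lo, units - (k - 1) * lo)), k - 1))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    last <- units - sum(grid[i, ])
    if (last < lo) next
    fr <- c(unlist(grid[i, ]), last) * step
    out[[length(out) + 1L]] <- stats::setNames(as.numeric(fr), tags)
  }
  out
}

#' Screen growth phenotypes across substrates
#'
#' For each substrate: opens its uptake at a fixed test bound, closes the
#' uptake of every other listed carbon source, and maximizes biomass.
#' Growth is called when the optimum exceeds `threshold`.
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param substrates Named list; each element is a character vector of
#'   exchange reaction ids opened together (e.g.
#'   `list("H2+CO2" = c("EX_h2_e", "EX_co2_e"))`).
#' @param uptake_bound Uptake lower bound applied to opened exchanges
#'   (default -10 mmol h^-1).
#' @param carbon_sources Exchange ids closed (lower bound 0) in every trial;
#'   defaults to the union of all substrate exchanges.
#' @param threshold Growth-call threshold on the biomass optimum.
#' @return `data.frame` with `substrate`, `growth` (logical; `NA` when the
#'   substrate has no exchange in the model = "not representable") and
#'   `objective_value`.
#' @export
phenotype_screen <- function(model, substrates, uptake_bound = -10,
                             carbon_sources = unique(unlist(substrates)),
                             threshold = 1e-6) {
  rows <- lapply(names(substrates), function(name) {
    ex <- substrates[[name]]
    if (!all(ex %in% model$reactions$id)) {
      return(data.frame(substrate = name, growth = NA,
                        objective_value = NA_real_))
    }
    m <- model
    closed <- intersect(setdiff(carbon_sources, ex), m$reactions$id)
    if (length(closed)) m <- set_bounds(m, closed, lower = 0)
    m <- set_bounds(m, ex, lower = uptake_bound)
    sol <- solve_fba(m, m$biomass_id, "max")
    data.frame(substrate = name,
               growth = if (sol$status == "optimal")
                 sol$objective_value > threshold else FALSE,
               objective_value = if (sol$status == "optimal")
                 sol$objective_value else NA_real_)
  })
  do.call(rbind, rows)
}
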
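# Scenario analyses: product profiles by flux sampling across species
# ratios and across H2 co-feeding levels.

.default_product_exchanges <- function(model) {
  ex <- model$reactions$id[is_exchange(model)]
  drop <- grepl("h2o|nh3|Biomass", ex)
  ex[!drop]
}

#' Product profiles across species ratios
#'
#' For each biomass ratio: re-parametrize the community biomass, apply the
#' chemostat condition, sample the flux polytope, and summarize exchange
#' fluxes. Infeasible ratios are recorded and the scan continues.
#'
#' @param cm A `community_model`.
#' @param ratio_list List of named fraction vectors summing to 1.
#' @param mu Growth rate (h^-1).
#' @param total_biomass Total biomass X (g).
#' @param exchange_bounds Named list of environmental exchange bounds, e.g.
#'   `list(EX_co_e = c(-3.5, -2.5))`.
#' @param n Samples per ratio.
#' @param seed Base seed (offset by the ratio index).
#' @param thinning Sampler thinning.
#' @param exchange_ids Exchanges to report (default: all except water,
#'   ammonia, biomass).
#' @return Tidy `data.frame`: one row per (ratio, product) with the
#'   fractions, `reaction_id`, `metabolite`, `mean`, `sd`, `feasible`.
#' @export
scan_ratios <- function(cm, ratio_list, mu, total_biomass,
                        exchange_bounds = list(), n = 1000, seed = 1,
                        thinning = 25, exchange_ids = NULL) {
  tags <- cm$species$tag
  if (is.null(exchange_ids)) exchange_ids <- .default_product_exchanges(cm)
  rows <- list()
  for (i in seq_along(ratio_list)) {
    fr <- ratio_list[[i]]
    if (abs(sum(fr) - 1) > 1e-9) stop("ratio ", i, " does not sum to 1")
    cond <- community_condition(mu, total_biomass, fr, exchange_bounds)
    constrained <- apply_condition(cm, cond)
    sol <- solve_fba(constrained)
    base <- data.frame(t(fr[tags]))
    names(base) <- tags
    if (sol$status != "optimal") {
      rows[[length(rows) + 1L]] <- cbind(
        base, data.frame(reaction_id = NA_character_,
                         metabolite = NA_character_, mean = NA_real_,
                         sd = NA_real_, feasible = sol$status == "optimal"))
      next
    }
    sr <- sample_fluxes(constrained, n = n, seed = seed + i,
                        thinning = thinning)
    prof <- product_profile(sr, exchange_ids, model = constrained)
    prof$feasible <- TRUE
    rows[[length(rows) + 1L]] <- cbind(base[rep(1, nrow(prof)), , drop = FALSE],
                                       prof)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Product profiles across H2 co-feeding levels
#'
#' For each H2 uptake level the H2 exchange flux is fixed at that level
#' (mmol h^-1, negative = uptake; 0 reproduces the CO-only scenario), the
#' condition is applied, and the polytope sampled. CO2 output is always
#' reported; on species models a Wood-Ljungdahl lump flux can be reported
#' alongside via `wl_reaction_id`.
#'
#' @param model A `community_model` (needs `fractions`) or a species
#'   `metabolic_model` run as monoculture.
#' @param co_bounds `c(lower, upper)` CO exchange bounds (mmol h^-1).
#' @param h2_levels Numeric vector of H2 uptake levels (<= 0).
#' @param h2_mode `"max_uptake"` (default) constrains the H2 exchange to
#'   `[level, 0]` — the level is an availability, like the CO interval;
#'   `"fixed"` pins the flux at the level exactly.
#' @param mu,total_biomass,n,seed,thinning,exchange_ids As in
#'   [scan_ratios()].
#' @param fractions Named fractions (community models only).
#' @param co_id,h2_id,co2_id Exchange reaction ids.
#' @param wl_reaction_id Optional reaction whose mean flux is reported
#'   (e.g. the Wood-Ljungdahl lump `"WLP"`).
#' @return Tidy `data.frame`: one row per (level, product) plus one
#'   `co2 output` row per level; columns `h2_level`, `co_h2_ratio`,
#'   `reaction_id`, `metabolite`, `mean`, `sd`, `feasible`, and `wl_flux`
#'   when requested.
#' @export
scan_h2 <- function(model, co_bounds, h2_levels, mu, total_biomass,
                    fractions = NULL, h2_mode = c("max_uptake", "fixed"),
                    n = 1000, seed = 1, thinning = 25,
                    exchange_ids = NULL, co_id = "EX_co_e",
                    h2_id = "EX_h2_e", co2_id = "EX_co2_e",
                    wl_reaction_id = NULL) {
  h2_mode <- match.arg(h2_mode)
  if (any(h2_levels > 0)) stop("h2_levels are uptake rates and must be <= 0")
  if (is.null(exchange_ids)) exchange_ids <- .default_product_exchanges(model)
  exchange_ids <- union(exchange_ids, co2_id)
  rows <- list()
  for (i in seq_along(h2_levels)) {
    h2 <- h2_levels[i]
    eb <- list()
    eb[[co_id]] <- co_bounds
    eb[[h2_id]] <- if (h2_mode == "fixed") c(h2, h2) else c(h2, 0)
    if (inherits(model, "community_model")) {
      if (is.null(fractions)) stop("community models need `fractions`")
      cond <- community_condition(mu, total_biomass, fractions, eb)
    } else {
      cond <- community_condition(mu, total_biomass, c(sp = 1), eb)
    }
    constrained <- apply_condition(model, cond)
    sol <- solve_fba(constrained)
    mean_co <- NA_real_
    if (sol$status != "optimal") {
      row <- data.frame(
        h2_level = h2, co_h2_ratio = NA_real_, reaction_id = NA_character_,
        metabolite = NA_character_, mean = NA_real_, sd = NA_real_,
        feasible = FALSE)
      if (!is.null(wl_reaction_id)) row$wl_flux <- NA_real_
      rows[[length(rows) + 1L]] <- row
      next
    }
    sr <- sample_fluxes(constrained, n = n, seed = seed + i,
                        thinning = thinning)
    prof <- product_profile(sr, exchange_ids, model = constrained)
    prof$feasible <- TRUE
    mean_co <- -mean(sr$samples[, co_id])  # uptake magnitude
    prof <- cbind(data.frame(h2_level = h2,
                             co_h2_ratio = if (h2 < 0) mean_co / -h2 else Inf),
                  prof)
    if (!is.null(wl_reaction_id)) {
      prof$wl_flux <- if (wl_reaction_id %in% sr$reaction_ids)
        mean(sr$samples[, wl_reaction_id]) else NA_real_
    }
    rows[[length(rows) + 1L]] <- prof
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
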
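# Community assembly: tag species compartments, merge single-species models
# over a shared extracellular pool, and parametrize a community biomass
# reaction by biomass (cell-dry-weight) fractions.

#' Declare one species of a community
#'
#' @param model A `metabolic_model` (untagged).
#' @param tag Short species identifier, e.g. `"aw"`; suffixed to all
#'   intracellular ids.
#' @param biomass_fraction Cell-dry-weight fraction of this species in the
#'   community, in (0, 1].
#' @return A `species_spec` list.
#' @export
species_spec <- function(model, tag, biomass_fraction) {
  stopifnot(inherits(model, "metabolic_model"),
            is.character(tag), nchar(tag) > 0,
            biomass_fraction > 0, biomass_fraction <= 1)
  structure(list(model = model, tag = tag,
                 biomass_fraction = biomass_fraction),
            class = "species_spec")
}

#' Tag a species model's intracellular namespace
#'
#' Suffixes every non-extracellular metabolite id, compartment id, and every
#' reaction that touches an intracellular metabolite with `"_<tag>"`
#' (`acetate` in the cytosol becomes `acetate_aw`). Extracellular ids and
#' pure exchange reactions are left untouched, so merged models share one
#' extracellular pool.
#'
#' @param model A `metabolic_model`.
#' @param tag Species tag.
#' @return The tagged model.
#' @export
tag_species <- function(model, tag) {
  suffix <- paste0("_", tag)
  comp_ids <- names(model$compartments)
  intra <- setdiff(comp_ids, model$extracellular_id)
  if (length(intra) == 0) stop("model has no intracellular compartment")
  if (any(endsWith(c(model$metabolites$id, model$reactions$id, intra),
                   suffix))) {
    stop("tag '", tag, "' collides with existing id suffixes")
  }
  met_intra <- model$metabolites$compartment != model$extracellular_id
  new_met <- ifelse(met_intra, paste0(model$metabolites$id, suffix),
                    model$metabolites$id)
  rxn_tagged <- as.vector(
    Matrix::colSums(model$S[met_intra, , drop = FALSE] != 0) > 0)
  new_rxn <- ifelse(rxn_tagged, paste0(model$reactions$id, suffix),
                    model$reactions$id)
  remap <- function(x, old, new) {
    i <- match(x, old); ifelse(is.na(i), x, new[i])
  }
  model$metabolites$id <- new_met
  model$metabolites$compartment <- remap(model$metabolites$compartment,
                                         intra, paste0(intra, suffix))
  model$reactions$id <- new_rxn
  names(model$compartments) <- remap(comp_ids, intra, paste0(intra, suffix))
  dimnames(model$S) <- list(new_met, new_rxn)
  for (field in c("objective_id", "biomass_id", "ngam_id")) {
    if (!is.na(model[[field]]) && paste0(model[[field]], suffix) %in% new_rxn) {
      model[[field]] <- paste0(model[[field]], suffix)
    }
  }
  attr(model, "species_tag") <- tag
  validate_model(model)
  model
}

#' Remove a species tag (inverse of [tag_species()])
#'
#' @param model A tagged `metabolic_model`.
#' @param tag The tag to strip.
#' @return The untagged model.
#' @export
untag_species <- function(model, tag) {
  suffix <- paste0("_", tag)
  strip <- function(x) sub(paste0(suffix, "$"), "", x)
  model$metabolites$id <- strip(model$metabolites$id)
  model$metabolites$compartment <- strip(model$metabolites$compartment)
  model$reactions$id <- strip(model$reactions$id)
  names(model$compartments) <- strip(names(model$compartments))
  dimnames(model$S) <- list(model$metabolites$id, model$reactions$id)
  for (field in c("objective_id", "biomass_id", "ngam_id")) {
    if (!is.na(model[[field]])) model[[field]] <- strip(model[[field]])
  }
  attr(model, "species_tag") <- NULL
  validate_model(model)
  model
}

#' Merge tagged species models into a community model
#'
#' Extracellular metabolites present in several inputs appear once;
#' duplicate exchange reactions are collapsed to a single reaction whose
#' bounds are the union interval (componentwise min of lower bounds, max of
#' upper bounds), so the community is never more restricted than any member.
#' Per-species transport reactions are preserved, so each species exchanges
#' with the shared pool. A community biomass reaction is added via
#' [add_community_biomass()].
#'
#' @param species List of [species_spec()] objects (at least two); fractions
#'   must sum to 1 within `1e-9`.
#' @param id Community model id.
#' @return A `community_model` (subclass of `metabolic_model` with a
#'   `species` table and `community_biomass_id`).
#' @export
merge_models <- function(species, id = "community") {
  stopifnot(length(species) >= 2)
  tags <- vapply(species, `[[`, character(1), "tag")
  if (anyDuplicated(tags)) stop("duplicate species tag: ",
                                tags[duplicated(tags)][1])
  fr <- vapply(species, `[[`, numeric(1), "biomass_fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("biomass fractions sum to ", sum(fr), ", not 1")
  }
  ex_id <- species[[1]]$model$extracellular_id
  tagged <- lapply(species, function(sp) {
    if (sp$model$extracellular_id != ex_id) {
      stop("species disagree on the extracellular compartment id")
    }
    tag_species(sp$model, sp$tag)
  })

  compartments <- character(0)
  mets <- list(); rxn_rows <- list()
  rxn_species <- character(0)
  stoich <- list()  # per reaction: named coefficient vector
  met_formula <- list()
  for (k in seq_along(tagged)) {
    tm <- tagged[[k]]
    compartments <- c(compartments, tm$compartments[
      setdiff(names(tm$compartments), names(compartments))])
    for (i in seq_len(nrow(tm$metabolites))) {
      mid <- tm$metabolites$id[i]
      if (!is.null(met_formula[[mid]])) {
        f_old <- met_formula[[mid]]; f_new <- tm$metabolites$formula[i]
        if (!is.na(f_old) && !is.na(f_new) && f_old != f_new) {
          stop("conflicting formulas for shared metabolite ", mid,
               ": ", f_old, " vs ", f_new)
        }
        next
      }
      met_formula[[mid]] <- tm$metabolites$formula[i]
      mets[[mid]] <- tm$metabolites[i, ]
    }
    exch <- is_exchange(tm)
    for (j in seq_len(nrow(tm$reactions))) {
      rid <- tm$reactions$id[j]
      row <- tm$reactions[j, ]
      if (!is.null(stoich[[rid]])) {
        # duplicate (necessarily extracellular/exchange): union bounds
        prev <- rxn_rows[[rid]]
        st_old <- stoich[[rid]]; st_new <- reaction_stoichiometry(tm, rid)
        if (!isTRUE(all.equal(st_old[order(names(st_old))],
                              st_new[order(names(st_new))], tolerance = 1e-9))) {
          stop("duplicate reaction id ", rid,
               " has conflicting stoichiometry across species")
        }
        prev$lower_bound <- min(prev$lower_bound, row$lower_bound)
        prev$upper_bound <- max(prev$upper_bound, row$upper_bound)
        rxn_rows[[rid]] <- prev
        next
      }
      stoich[[rid]] <- reaction_stoichiometry(tm, rid)
      rxn_rows[[rid]] <- row
      rxn_species[rid] <- if (exch[j]) NA_character_ else tags[k]
    }
  }
  met_df <- do.call(rbind, mets)
  rxn_df <- do.call(rbind, rxn_rows)
  rownames(met_df) <- rownames(rxn_df) <- NULL
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(rxn_df))) {
    st <- stoich[[rxn_df$id[j]]]
    ii <- c(ii, match(names(st), met_df$id))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(met_df), nrow(rxn_df)))
  cm <- metabolic_model(
    id = id, compartments = compartments, metabolites = met_df,
    reactions = rxn_df, stoichiometry = S,
    objective_id = NA_character_, biomass_id = NA_character_,
    extracellular_id = ex_id)
  cm$species <- data.frame(
    tag = tags,
    biomass_id = vapply(tagged, `[[`, character(1), "biomass_id"),
    fraction = fr, stringsAsFactors = FALSE)
  cm$rxn_species <- rxn_species[rxn_df$id]
  cm$community_biomass_id <- NA_character_
  class(cm) <- c("community_model", class(cm))
  add_community_biomass(cm, stats::setNames(fr, tags))
}

#' Set or re-parametrize the community biomass reaction
#'
#' Adds (or replaces) the reaction `EX_Biomass_e`, which consumes
#' `fraction_i` grams of each species' biomass metabolite per gram of
#' community biomass, and makes it the model objective. Coefficients are
#' scaled by each species biomass reaction's own production coefficient, so
#' fixing species biomass flux to `fraction_i * X * mu` and community
#' biomass flux to `X * mu` is consistent by construction.
#'
#' @param cm A `community_model`.
#' @param fractions Named numeric vector, tag -> fraction; must sum to 1
#'   within `1e-9`.
#' @return The re-parametrized `community_model`.
#' @export
add_community_biomass <- function(cm, fractions) {
  stopifnot(inherits(cm, "community_model"))
  if (!setequal(names(fractions), cm$species$tag)) {
    stop("fractions must be named by the species tags: ",
         paste(cm$species$tag, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions sum to ", sum(fractions), ", not 1")
  }
  fractions <- fractions[cm$species$tag]
  # species-biomass metabolite and its production coefficient per species
  bm_met <- character(nrow(cm$species)); bm_coef <- numeric(nrow(cm$species))
  for (k in seq_len(nrow(cm$species))) {
    st <- reaction_stoichiometry(cm, cm$species$biomass_id[k])
    prod <- st[st > 0]
    bm_candidates <- prod[grepl("^biomass|^Biomass", names(prod))]
    if (length(bm_candidates) == 0) bm_candidates <- prod
    if (length(bm_candidates) != 1) {
      stop("cannot identify the biomass metabolite produced by ",
           cm$species$biomass_id[k])
    }
    bm_met[k] <- names(bm_candidates); bm_coef[k] <- bm_candidates
  }
  rid <- "EX_Biomass_e"
  coef <- -as.numeric(fractions) * bm_coef
  if (rid %in% cm$reactions$id) {
    cm$S[bm_met, rid] <- coef
  } else {
    cm$reactions <- rbind(cm$reactions, data.frame(
      id = rid, name = "community biomass", lower_bound = 0,
      upper_bound = .LP_BIG, gene_rule = NA_character_,
      stringsAsFactors = FALSE))
    newcol <- Matrix::sparseMatrix(
      i = match(bm_met, cm$metabolites$id), j = rep(1L, length(bm_met)),
      x = coef, dims = c(nrow(cm$metabolites), 1L))
    cm$S <- cbind(cm$S, newcol)
    dimnames(cm$S) <- list(cm$metabolites$id, cm$reactions$id)
    cm$rxn_species <- c(cm$rxn_species, stats::setNames(NA_character_, rid))
  }
  cm$species$fraction <- as.numeric(fractions)
  cm$community_biomass_id <- rid
  cm$objective_id <- rid
  cm$biomass_id <- rid
  validate_model(cm)
  cm
}

#' Define a cFBA scenario
#'
#' @param growth_rate Community growth rate mu (h^-1, equal to the chemostat
#'   dilution rate); nonnegative.
#' @param total_biomass Total community biomass X (g); positive.
#' @param fractions Named numeric vector tag -> biomass fraction, summing
#'   to 1.
#' @param exchange_bounds Named list of `c(lower, upper)` environmental
#'   bounds (mmol h^-1) for exchange reactions, e.g.
#'   `list(EX_co_e = c(-3.5, -1))`.
#' @param objective_id Optional objective override (default: community
#'   biomass).
#' @return A `community_condition` list.
#' @export
community_condition <- function(growth_rate, total_biomass, fractions,
                                exchange_bounds = list(),
                                objective_id = NULL) {
  if (growth_rate < 0) stop("growth_rate must be >= 0")
  if (total_biomass <= 0) stop("total_biomass must be > 0")
  if (length(fractions) == 0) stop("fractions must be nonempty")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions sum to ", sum(fractions), ", not 1")
  }
  for (b in exchange_bounds) {
    if (length(b) != 2 || b[1] > b[2]) {
      stop("each exchange bound must be c(lower, upper) with lower <= upper")
    }
  }
  structure(list(growth_rate = growth_rate, total_biomass = total_biomass,
                 fractions = fractions, exchange_bounds = exchange_bounds,
                 objective_id = objective_id),
            class = "community_condition")
}

#' Apply a chemostat-style condition to a model
#'
#' Converts specific flux bounds (mmol gCDW^-1 h^-1) to environmental
#' bounds (mmol h^-1) by multiplying every finite per-species bound by
#' `X * fraction_i`, fixes each species biomass flux to
#' `fraction_i * X * mu` (g h^-1), fixes the community biomass flux to
#' `X * mu`, and installs the condition's exchange bounds. Pure: the
#' original model's unscaled ("specific") bounds are stashed on first
#' application, so applying the same condition twice equals applying it
#' once.
#'
#' @param model A `community_model`, or a plain `metabolic_model` treated
#'   as a monoculture (single fraction 1).
#' @param cond A [community_condition()].
#' @param big_bound Magnitude at or above which a bound is treated as an
#'   "unbounded" sentinel and left unscaled (default 1000).
#' @return A constrained copy of the model.
#' @export
apply_condition <- function(model, cond, big_bound = 1000) {
  UseMethod("apply_condition")
}

#' @export
apply_condition.community_model <- function(model, cond, big_bound = 1000) {
  stopifnot(inherits(cond, "community_condition"))
  if (!setequal(names(cond$fractions), model$species$tag)) {
    stop("condition fractions must be named by tags: ",
         paste(model$species$tag, collapse = ", "))
  }
  model <- add_community_biomass(model, cond$fractions)
  model <- .restore_specific_bounds(model)
  X <- cond$total_biomass; mu <- cond$growth_rate
  fr <- cond$fractions[model$species$tag]
  sp_of_rxn <- model$rxn_species[model$reactions$id]
  for (k in seq_len(nrow(model$species))) {
    tag <- model$species$tag[k]
    idx <- which(!is.na(sp_of_rxn) & sp_of_rxn == tag)
    sc <- X * fr[[tag]]
    lb <- model$reactions$lower_bound[idx]
    ub <- model$reactions$upper_bound[idx]
    model$reactions$lower_bound[idx] <- ifelse(abs(lb) >= big_bound, lb, lb * sc)
    model$reactions$upper_bound[idx] <- ifelse(abs(ub) >= big_bound, ub, ub * sc)
    bid <- model$species$biomass_id[k]
    model <- set_bounds(model, bid, lower = sc * mu, upper = sc * mu)
  }
  model <- set_bounds(model, model$community_biomass_id,
                      lower = X * mu, upper = X * mu)
  model <- .apply_exchange_bounds(model, cond$exchange_bounds)
  if (!is.null(cond$objective_id)) model$objective_id <- cond$objective_id
  validate_model(model)
  model
}

#' @export
apply_condition.metabolic_model <- function(model, cond, big_bound = 1000) {
  stopifnot(inherits(cond, "community_condition"))
  model <- .restore_specific_bounds(model)
  X <- cond$total_biomass
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  scale_row <- !is_exchange(model) & model$reactions$id != model$biomass_id
  model$reactions$lower_bound <- ifelse(
    scale_row & abs(lb) < big_bound, lb * X, lb)
  model$reactions$upper_bound <- ifelse(
    scale_row & abs(ub) < big_bound, ub * X, ub)
  if (!is.na(model$biomass_id)) {
    model <- set_bounds(model, model$biomass_id,
                        lower = X * cond$growth_rate,
                        upper = X * cond$growth_rate)
  }
  model <- .apply_exchange_bounds(model, cond$exchange_bounds)
  if (!is.null(cond$objective_id)) model$objective_id <- cond$objective_id
  validate_model(model)
  model
}

.restore_specific_bounds <- function(model) {
  stash <- attr(model, "specific_bounds")
  if (is.null(stash)) {
    attr(model, "specific_bounds") <- model$reactions[
      , c("id", "lower_bound", "upper_bound")]
    return(model)
  }
  idx <- match(model$reactions$id, stash$id)
  hit <- !is.na(idx)
  model$reactions$lower_bound[hit] <- stash$lower_bound[idx[hit]]
  model$reactions$upper_bound[hit] <- stash$upper_bound[idx[hit]]
  model
}

.apply_exchange_bounds <- function(model, exchange_bounds) {
  for (rid in names(exchange_bounds)) {
    b <- exchange_bounds[[rid]]
    if (!rid %in% model$reactions$id) stop("unknown exchange reaction: ", rid)
    model <- set_bounds(model, rid, lower = b[1], upper = b[2])
  }
  model
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$id, "\n", sep = "")
  cat("  species: ",
      paste(sprintf("%s (%.2f)", x$species$tag, x$species$fraction),
            collapse = ", "), "\n", sep = "")
  NextMethod()
}
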
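#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric network with typed
#' compartments, flux bounds and an objective. Stoichiometry is held as a
#' sparse metabolite-by-reaction matrix (negative coefficient = consumed,
#' positive = produced). Flux units are mmol h^-1 per unit flux in community
#' ("environmental") mode and mmol gCDW^-1 h^-1 in species ("specific")
#' mode; biomass reactions are scaled so one unit of flux makes 1 g CDW h^-1.
#'
#' @param id Model identifier.
#' @param compartments Named character vector, id -> name. Must contain the
#'   extracellular compartment.
#' @param metabolites `data.frame` with columns `id`, `name`, `formula`
#'   (string, `NA` allowed), `charge` (integer, `NA` allowed), `compartment`.
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule` (`NA` allowed).
#' @param stoichiometry Sparse or dense matrix, metabolites x reactions, with
#'   dimnames matching the two tables.
#' @param objective_id,biomass_id Reaction ids; `biomass_id` defaults to
#'   `objective_id`.
#' @param ngam_id Optional id of the non-growth-associated maintenance
#'   (NGAM) ATP-hydrolysis reaction.
#' @param extracellular_id Compartment id of the shared extracellular space
#'   (default `"e"`).
#' @return An object of class `metabolic_model`.
#' @seealso [read_tabular()], [read_sbml()], [validate_model()]
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, objective_id,
                            biomass_id = objective_id, ngam_id = NA_character_,
                            extracellular_id = "e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "formula")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  }
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(reactions$name)) reactions$name <- NA_character_
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- NA_character_
  S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(
    list(id = id, compartments = compartments,
         metabolites = metabolites, reactions = reactions, S = S,
         objective_id = objective_id, biomass_id = biomass_id,
         ngam_id = ngam_id, extracellular_id = extracellular_id),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, bound ordering, compartment references, that the
#' stoichiometric matrix matches the tables, that every reaction has
#' nonempty stoichiometry, and that the objective and biomass reactions
#' exist. Called by all constructors; exported for use after manual edits.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1])
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1])
  }
  bad <- !mets$compartment %in% names(model$compartments)
  if (any(bad)) {
    stop("metabolite ", mets$id[bad][1], " references undeclared compartment ",
         mets$compartment[bad][1])
  }
  if (!model$extracellular_id %in% names(model$compartments)) {
    stop("extracellular compartment '", model$extracellular_id,
         "' not declared")
  }
  if (anyNA(rxns$lower_bound) || anyNA(rxns$upper_bound)) {
    i <- which(is.na(rxns$lower_bound) | is.na(rxns$upper_bound))[1]
    stop("reaction ", rxns$id[i], " is missing a flux bound")
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    i <- which(rxns$lower_bound > rxns$upper_bound)[1]
    stop("reaction ", rxns$id[i], " has lower_bound > upper_bound")
  }
  if (!identical(dim(model$S), c(nrow(mets), nrow(rxns)))) {
    stop("stoichiometric matrix dimensions do not match the tables")
  }
  rn <- rownames(model$S); cn <- colnames(model$S)
  if (!identical(if (is.null(rn)) character(0) else rn, mets$id) ||
      !identical(if (is.null(cn)) character(0) else cn, rxns$id)) {
    stop("stoichiometric matrix dimnames do not match the tables")
  }
  if (nrow(rxns)) {
    nnz <- Matrix::colSums(model$S != 0)
    if (any(nnz == 0)) {
      stop("reaction ", rxns$id[which(nnz == 0)[1]],
           " has empty stoichiometry")
    }
  }
  for (field in c("objective_id", "biomass_id")) {
    rid <- model[[field]]
    if (!is.na(rid) && !rid %in% rxns$id) {
      stop(field, " '", rid, "' is not a reaction in the model")
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", paste(names(x$compartments), collapse = ", "), "\n",
      sep = "")
  cat("  metabolites:  ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:    ", nrow(x$reactions),
      " (", sum(is_exchange(x)), " exchange)\n", sep = "")
  cat("  objective:    ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Flag exchange reactions
#'
#' A reaction is an exchange iff it touches exactly one metabolite and that
#' metabolite lies in the extracellular compartment. An explicit id list can
#' override the structural rule.
#'
#' @param model A `metabolic_model`.
#' @param exchange_ids Optional character vector naming the exchanges
#'   explicitly (overrides detection).
#' @return Logical vector along `model$reactions`.
#' @export
is_exchange <- function(model, exchange_ids = NULL) {
  if (!is.null(exchange_ids)) {
    return(model$reactions$id %in% exchange_ids)
  }
  if (nrow(model$reactions) == 0) return(logical(0))
  nnz <- Matrix::colSums(model$S != 0)
  extra <- model$metabolites$compartment == model$extracellular_id
  one_extra <- Matrix::colSums(model$S[extra, , drop = FALSE] != 0)
  as.vector(nnz == 1 & one_extra == 1)
}

#' Stoichiometry of one reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @return Named numeric vector of nonzero coefficients
#'   (negative = consumed).
#' @export
reaction_stoichiometry <- function(model, reaction_id) {
  if (!reaction_id %in% model$reactions$id) {
    stop("unknown reaction id: ", reaction_id)
  }
  col <- model$S[, reaction_id]
  col <- col[col != 0]
  stats::setNames(as.numeric(col), names(col))
}

#' Set flux bounds on reactions
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Character vector of reaction ids.
#' @param lower,upper Numeric vectors (recycled) of new bounds; `NA` leaves
#'   the existing bound untouched.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_ids, lower = NA, upper = NA) {
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id: ", reaction_ids[is.na(idx)][1])
  }
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  keep <- !is.na(lower)
  model$reactions$lower_bound[idx[keep]] <- lower[keep]
  keep <- !is.na(upper)
  model$reactions$upper_bound[idx[keep]] <- upper[keep]
  validate_model(model)
}

#' Number of reactions / metabolites
#' @param model A `metabolic_model`.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

# Internal: models compare equal up to row/column order and attribute noise.
model_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!setequal(a$reactions$id, b$reactions$id)) return(FALSE)
  am <- a$metabolites[order(a$metabolites$id), ]
  bm <- b$metabolites[order(b$metabolites$id), ]
  same_chr <- function(x, y) all(ifelse(is.na(x), is.na(y), !is.na(y) & x == y))
  if (!same_chr(am$formula, bm$formula)) return(FALSE)
  if (!same_chr(am$compartment, bm$compartment)) return(FALSE)
  ar <- a$reactions[order(a$reactions$id), ]
  br <- b$reactions[order(b$reactions$id), ]
  if (max(abs(ar$lower_bound - br$lower_bound),
          abs(ar$upper_bound - br$upper_bound)) > tol) return(FALSE)
  Sa <- a$S[am$id, ar$id, drop = FALSE]
  Sb <- b$S[am$id, ar$id, drop = FALSE]
  if (max(abs(Sa - Sb)) > tol) return(FALSE)
  isTRUE(a$objective_id == b$objective_id) || (is.na(a$objective_id) && is.na(b$objective_id))
}
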
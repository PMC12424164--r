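#' Parse a reaction equation string
#'
#' Equations use the dialect `"2 co2_aw + 8 red_aw -> acetyl_aw"`. The
#' separator `->` (or `<->`, equivalent here: reversibility is carried by the
#' bounds, not the arrow) splits substrates from products; either side may be
#' empty, as in the exchange `"co_e ->"`. Coefficients default to 1.
#'
#' @param equation Equation string.
#' @return Named numeric vector of coefficients, negative for substrates.
#' @examples
#' parse_reaction_equation("co_c + h2o_c -> co2_c + red_c")
#' @export
parse_reaction_equation <- function(equation) {
  sides <- strsplit(equation, "<->|<=>|-->|->", perl = TRUE)[[1]]
  if (!grepl("<->|<=>|-->|->", equation)) {
    stop("equation has no '->' separator: ", equation)
  }
  if (length(sides) > 2) stop("equation has multiple arrows: ", equation)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(txt, "\\+")[[1]])
    coefs <- numeric(length(terms))
    ids <- character(length(terms))
    for (i in seq_along(terms)) {
      parts <- strsplit(terms[i], "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        coefs[i] <- 1; ids[i] <- parts
      } else if (length(parts) == 2) {
        cf <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(cf)) stop("cannot parse coefficient in term '", terms[i],
                            "' of equation: ", equation)
        coefs[i] <- cf; ids[i] <- parts[2]
      } else {
        stop("cannot parse term '", terms[i], "' in equation: ", equation)
      }
    }
    stats::setNames(sign * coefs, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], 1) else
    stats::setNames(numeric(0), character(0))
  out <- c(lhs, rhs)
  if (length(out) == 0) stop("equation is empty: ", equation)
  if (anyDuplicated(names(out))) {
    # same metabolite on both sides: net it out
    agg <- tapply(out, names(out), sum)[unique(names(out))]
    out <- stats::setNames(as.numeric(agg), names(agg))
    out <- out[out != 0]
    if (length(out) == 0) stop("equation cancels to nothing: ", equation)
  }
  out
}

#' Format a reaction as an equation string
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @return Equation string in the dialect of [parse_reaction_equation()].
#' @export
format_reaction_equation <- function(model, reaction_id) {
  st <- reaction_stoichiometry(model, reaction_id)
  fmt <- function(v) {
    if (length(v) == 0) return("")
    paste(ifelse(v == 1, names(v),
                 paste(sub("\\.?0+$", "", format(v, trim = TRUE, digits = 12)),
                       names(v))),
          collapse = " + ")
  }
  paste(fmt(-st[st < 0]), "->", fmt(st[st > 0]))
}

#' Build a model from equation strings
#'
#' Convenience constructor used by the tabular reader and the toy-community
#' generators: metabolites are given as a table, reactions as equations.
#'
#' @param id Model id.
#' @param compartments Named character vector of compartments.
#' @param metabolites `data.frame` with at least `id` and `compartment`;
#'   optional `name`, `formula`, `charge`.
#' @param reactions `data.frame` with `id`, `equation`, `lower_bound`,
#'   `upper_bound`; optional `name`, `gene_rule`.
#' @param ... Passed to [metabolic_model()] (`objective_id`, `biomass_id`,
#'   `ngam_id`, `extracellular_id`).
#' @return A `metabolic_model`.
#' @export
model_from_equations <- function(id, compartments, metabolites, reactions, ...) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(reactions))) {
    st <- tryCatch(parse_reaction_equation(reactions$equation[j]),
                   error = function(e) {
                     stop("reaction ", reactions$id[j], " (line ", j, "): ",
                          conditionMessage(e), call. = FALSE)
                   })
    miss <- setdiff(names(st), metabolites$id)
    if (length(miss)) {
      stop("reaction ", reactions$id[j], " (line ", j,
           ") references unknown metabolite id: ", miss[1], call. = FALSE)
    }
    ii <- c(ii, match(names(st), metabolites$id))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nrow(reactions)))
  reactions$equation <- NULL
  metabolic_model(id = id, compartments = compartments,
                  metabolites = metabolites, reactions = reactions,
                  stoichiometry = S, ...)
}
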
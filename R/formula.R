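#' @title Chemical formula utilities
#' @name formula-utils
#' @description Parse and format empirical formulas of the form `"C2H4O2"`.
#' Formulas are stored on metabolites as plain strings; an empty string
#' denotes a defined but element-free species (used for lumped energy
#' tokens such as ATP), while `NA` means the formula is unknown.
NULL

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
                  S = 32.06, Fe = 55.845, Na = 22.99, K = 39.098, Mg = 24.305)

#' Parse an empirical formula string
#'
#' @param formula A formula string such as `"C2H4O2"` or `"CO2"`. Counts may
#'   be omitted (1) and may be non-integer (e.g. biomass pseudo-formulas).
#' @return A named numeric vector of element counts; `numeric(0)` for the
#'   empty string; `NULL` for `NA` input.
#' @examples
#' parse_formula("C2H4O2")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() expects a single string")
  if (is.na(formula)) return(NULL)
  if (!nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  if (anyNA(ct) || any(ct < 0)) stop("invalid element count in formula: ", formula)
  out <- tapply(ct, el, sum)[unique(el)]
  stats::setNames(as.numeric(out), names(out))
}

#' Format element counts as a formula string
#'
#' @param counts Named numeric vector of element counts.
#' @return A single string; elements in C, H, then alphabetical order.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0) return("")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  paste0(names(counts),
         ifelse(counts == 1, "", sub("\\.?0+$", "", format(counts, trim = TRUE))),
         collapse = "")
}

#' Molar mass of a formula
#'
#' @param formula Formula string.
#' @return Mass in g/mol.
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) stop("molar_mass() needs a non-missing formula")
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown)) stop("no atomic mass for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * counts)
}
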
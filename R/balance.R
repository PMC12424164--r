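#' Check elemental balance of all reactions
#'
#' Computes, for every internal reaction, the per-element net
#' `sum(coefficient * element count)` and reports reactions with any nonzero
#' net. Exchange reactions, other single-metabolite boundary reactions
#' (demand/sink), and the biomass reaction(s) are excluded: they are
#' unbalanced by construction. Reactions touching a metabolite with an
#' unknown (`NA`) formula are reported as `"unchecked"` rather than failed.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute tolerance on a per-element net (default `1e-6`).
#' @param exclude Extra reaction ids to exclude.
#' @return A `data.frame` (class `elemental_balance_report`) with one row
#'   per reaction: `reaction_id`, `status`
#'   (`balanced`/`imbalanced`/`unchecked`/`excluded`) and `imbalance`
#'   (a string such as `"O:+1"`, empty when balanced).
#' @examples
#' m <- make_toy_acetogen()
#' subset(check_elemental_balance(m), status == "imbalanced")
#' @export
check_elemental_balance <- function(model, tol = 1e-6, exclude = character(0)) {
  mets <- model$metabolites
  rxns <- model$reactions
  counts <- lapply(mets$formula, function(f) {
    if (is.na(f)) NULL else parse_formula(f)
  })
  has_formula <- !vapply(counts, is.null, logical(1))
  elements <- unique(unlist(lapply(counts, names)))
  E <- matrix(0, nrow = length(elements), ncol = nrow(mets),
              dimnames = list(elements, mets$id))
  for (i in which(has_formula)) {
    ct <- counts[[i]]
    E[names(ct), i] <- ct
  }
  nnz <- Matrix::colSums(model$S != 0)
  boundary <- nnz == 1
  biomass_like <- rxns$id %in% c(model$biomass_id, exclude)
  net <- E %*% model$S  # elements x reactions
  status <- character(nrow(rxns))
  imbalance <- character(nrow(rxns))
  for (j in seq_len(nrow(rxns))) {
    if (boundary[j] || biomass_like[j]) {
      status[j] <- "excluded"
    } else {
      st <- model$S[, j]
      touched <- which(st != 0)
      if (any(!has_formula[touched])) {
        status[j] <- "unchecked"
      } else {
        dev <- net[, j]
        bad <- abs(dev) > tol
        if (any(bad)) {
          status[j] <- "imbalanced"
          imbalance[j] <- paste0(elements[bad], ":",
                                 ifelse(dev[bad] > 0, "+", ""),
                                 signif(dev[bad], 6), collapse = ", ")
        } else {
          status[j] <- "balanced"
        }
      }
    }
  }
  out <- data.frame(reaction_id = rxns$id, status = status,
                    imbalance = imbalance, stringsAsFactors = FALSE)
  class(out) <- c("elemental_balance_report", "data.frame")
  out
}

#' @export
print.elemental_balance_report <- function(x, ...) {
  tab <- table(x$status)
  cat("<elemental_balance_report> ", nrow(x), " reactions: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  bad <- x[x$status == "imbalanced", , drop = FALSE]
  if (nrow(bad)) {
    cat("imbalanced reactions:\n")
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}
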
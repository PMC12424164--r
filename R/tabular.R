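# Tabular model dialect: one JSON document, or a pair of TSV tables
# (<prefix>_metabolites.tsv + <prefix>_reactions.tsv). Reactions are given
# as equation strings in the dialect of parse_reaction_equation().

#' Read a model from the tabular dialect
#'
#' `path` ending in `.json` selects the JSON document form; otherwise it is
#' taken as a prefix and `<path>_metabolites.tsv` /
#' `<path>_reactions.tsv` are read.
#'
#' @param path JSON path or TSV prefix.
#' @return A [metabolic_model()].
#' @export
read_tabular <- function(path) {
  if (grepl("\\.json$", path)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    mets <- as.data.frame(doc$metabolites, stringsAsFactors = FALSE)
    rxns <- as.data.frame(doc$reactions, stringsAsFactors = FALSE)
    compartments <- unlist(doc$compartments)
    meta <- doc
  } else {
    mpath <- paste0(path, "_metabolites.tsv")
    rpath <- paste0(path, "_reactions.tsv")
    for (p in c(mpath, rpath)) if (!file.exists(p)) stop("missing file: ", p)
    # model-level ids live in a "# model id=... objective_id=..." comment on
    # the first line of the metabolite table
    hdr <- readLines(mpath, n = 1L)
    meta <- list(id = "model", objective_id = NA, biomass_id = NA,
                 ngam_id = NA, extracellular_id = "e")
    skip <- 0L
    if (startsWith(hdr, "#")) {
      skip <- 1L
      kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ,|]+", hdr))[[1]]
      for (item in kv) {
        parts <- strsplit(item, "=", fixed = TRUE)[[1]]
        meta[[parts[1]]] <- parts[2]
      }
    }
    mets <- utils::read.delim(mpath, stringsAsFactors = FALSE, skip = skip,
                              na.strings = "NA")
    rxns <- utils::read.delim(rpath, stringsAsFactors = FALSE,
                              na.strings = "NA")
    compartments <- sort(unique(mets$compartment))
    names(compartments) <- compartments
    rxns$gene_rule <- if (is.null(rxns$gene_rule)) NA_character_ else rxns$gene_rule
  }
  if (is.null(meta$extracellular_id) || is.na(meta$extracellular_id)) {
    meta$extracellular_id <- "e"
  }
  if (!is.null(mets$formula)) mets$formula <- as.character(mets$formula)
  model_from_equations(
    id = if (is.null(meta$id)) "model" else meta$id,
    compartments = compartments, metabolites = mets, reactions = rxns,
    objective_id = if (is.null(meta$objective_id)) NA_character_ else
      as.character(meta$objective_id),
    biomass_id = if (is.null(meta$biomass_id)) NA_character_ else
      as.character(meta$biomass_id),
    ngam_id = if (is.null(meta$ngam_id)) NA_character_ else
      as.character(meta$ngam_id),
    extracellular_id = meta$extracellular_id)
}

#' Write a model in the tabular dialect
#'
#' @param model A `metabolic_model`.
#' @param path Output path; `.json` selects the JSON form, anything else is
#'   used as a TSV prefix.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(model, path) {
  validate_model(model)
  if (n_reactions(model) == 0) stop("refusing to write a model with no reactions")
  rxns <- model$reactions
  rxns$equation <- vapply(rxns$id, function(r) format_reaction_equation(model, r),
                          character(1))
  rxns <- rxns[, c("id", "name", "equation", "lower_bound", "upper_bound",
                   "gene_rule")]
  if (grepl("\\.json$", path)) {
    doc <- list(id = model$id,
                compartments = as.list(model$compartments),
                metabolites = model$metabolites,
                reactions = rxns,
                objective_id = model$objective_id,
                biomass_id = model$biomass_id,
                ngam_id = model$ngam_id,
                extracellular_id = model$extracellular_id)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    hdr <- paste0("# model id=", model$id,
                  " objective_id=", model$objective_id,
                  " biomass_id=", model$biomass_id,
                  " ngam_id=", model$ngam_id,
                  " extracellular_id=", model$extracellular_id)
    mpath <- paste0(path, "_metabolites.tsv")
    writeLines(hdr, mpath)
    suppressWarnings(utils::write.table(
      model$metabolites, mpath, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
    utils::write.table(rxns, paste0(path, "_reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
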
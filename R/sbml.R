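# SBML Level 3 (FBC subset) I/O on top of xml2.
#
# Scope: compartments, species (with fbc chemical formula / charge),
# reactions with flux bounds and an active fbc objective. Bounds are
# accepted in both common encodings: fbc-v2 lowerFluxBound/upperFluxBound
# attributes referencing global parameters, and fbc-v1 listOfFluxBounds.
# Annotations, SBO terms and full gene-product association trees are out of
# scope; a raw rule string is carried when present.

.SBML_NS <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc2 = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  fbc1 = "http://www.sbml.org/sbml/level3/version1/fbc/version1"
)

#' Read an SBML Level 3 model
#'
#' @param path Path to an SBML file (Level 3, FBC flux bounds and
#'   objectives).
#' @param biomass_pattern,ngam_pattern Regular expressions used to locate
#'   the biomass and NGAM reactions when no objective annotation settles it.
#' @param extracellular_id Compartment id of the extracellular space;
#'   guessed from ids ending in `"e"` when `NULL`.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, biomass_pattern = "^Biomass|^biomass",
                      ngam_pattern = "rxn00062", extracellular_id = NULL) {
  doc <- xml2::read_xml(path)  # malformed XML errors here
  ns <- .SBML_NS
  model_node <- xml2::xml_find_first(doc, "//s:model", ns)
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)
  grab <- function(node, attr) xml2::xml_attr(node, attr)
  # fbc attributes, accepting either fbc version prefix (or none)
  fbc_attr <- function(node, attr) {
    v <- xml2::xml_attr(node, paste0("fbc2:", attr), ns = ns)
    miss <- is.na(v)
    if (any(miss)) {
      v2 <- xml2::xml_attr(node, paste0("fbc1:", attr), ns = ns)
      v[miss] <- v2[miss]
      miss <- is.na(v)
    }
    if (any(miss)) v[miss] <- xml2::xml_attr(node, attr)[miss]
    v
  }

  comp_nodes <- xml2::xml_find_all(doc, "//s:listOfCompartments/s:compartment", ns)
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  compartments <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")), comp_ids,
           xml2::xml_attr(comp_nodes, "name")), comp_ids)

  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = fbc_attr(sp_nodes, "chemicalFormula"),
    charge = suppressWarnings(as.integer(fbc_attr(sp_nodes, "charge"))),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))

  # fbc-v1 flux bound encoding
  fb_nodes <- xml2::xml_find_all(
    doc, "//fbc1:listOfFluxBounds/fbc1:fluxBound", ns)
  fb1 <- data.frame(
    reaction = xml2::xml_attr(fb_nodes, "reaction"),
    operation = xml2::xml_attr(fb_nodes, "operation"),
    value = as.numeric(xml2::xml_attr(fb_nodes, "value")),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  nr <- length(rx_nodes)
  rid <- xml2::xml_attr(rx_nodes, "id")
  rname <- xml2::xml_attr(rx_nodes, "name")
  lbv <- numeric(nr); ubv <- numeric(nr); rule <- character(nr)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    node <- rx_nodes[[j]]
    lb_ref <- fbc_attr(node, "lowerFluxBound")
    ub_ref <- fbc_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && !is.na(ub_ref)) {
      if (!lb_ref %in% names(par_val) || !ub_ref %in% names(par_val)) {
        stop("reaction ", rid[j], ": flux-bound parameter not found")
      }
      lbv[j] <- par_val[[lb_ref]]; ubv[j] <- par_val[[ub_ref]]
    } else if (nrow(fb1) && rid[j] %in% fb1$reaction) {
      rows <- fb1[fb1$reaction == rid[j], ]
      lo <- rows$value[rows$operation %in% c("greaterEqual", "equal")]
      hi <- rows$value[rows$operation %in% c("lessEqual", "equal")]
      if (!length(lo) || !length(hi)) {
        stop("reaction ", rid[j], " is missing a flux bound")
      }
      lbv[j] <- max(lo); ubv[j] <- min(hi)
    } else {
      stop("reaction ", rid[j], " is missing a flux bound")
    }
    rule[j] <- NA_character_
    gpa <- xml2::xml_find_first(node, ".//fbc2:geneProductAssociation", ns)
    if (!is.na(xml2::xml_name(gpa))) rule[j] <- xml2::xml_text(gpa)
    for (side in c("s:listOfReactants/s:speciesReference",
                   "s:listOfProducts/s:speciesReference")) {
      refs <- xml2::xml_find_all(node, side, ns)
      if (!length(refs)) next
      sgn <- if (grepl("Reactants", side)) -1 else 1
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      met_idx <- match(xml2::xml_attr(refs, "species"), metabolites$id)
      if (anyNA(met_idx)) {
        stop("reaction ", rid[j], " references unknown species")
      }
      ii <- c(ii, met_idx); jj <- c(jj, rep.int(j, length(refs)))
      xx <- c(xx, sgn * st)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nr))

  obj_refs <- xml2::xml_find_all(
    doc, "//fbc2:listOfObjectives//fbc2:fluxObjective | //fbc1:listOfObjectives//fbc1:fluxObjective",
    ns)
  objective_id <- NA_character_
  if (length(obj_refs)) objective_id <- fbc_attr(obj_refs[[1]], "reaction")
  biomass_id <- rid[grepl(biomass_pattern, rid)][1]
  if (is.na(biomass_id)) biomass_id <- objective_id
  if (is.na(objective_id)) objective_id <- biomass_id
  ngam_id <- rid[grepl(ngam_pattern, rid)][1]
  if (is.null(extracellular_id)) {
    cand <- comp_ids[comp_ids %in% c("e", "C_e", "extracellular") |
                       grepl("(^|_)e$", comp_ids)]
    extracellular_id <- if (length(cand)) cand[1] else comp_ids[1]
  }
  metabolic_model(
    id = if (!is.na(grab(model_node, "id"))) grab(model_node, "id") else "model",
    compartments = compartments, metabolites = metabolites,
    reactions = data.frame(id = rid, name = rname, lower_bound = lbv,
                           upper_bound = ubv, gene_rule = rule,
                           stringsAsFactors = FALSE),
    stoichiometry = S, objective_id = objective_id, biomass_id = biomass_id,
    ngam_id = ngam_id, extracellular_id = extracellular_id)
}

#' Write a model as SBML Level 3 with FBC version 2
#'
#' Bounds are emitted as global parameters referenced from
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`; the objective as an active
#' maximization objective. Refuses to write a model with no reactions.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  if (n_reactions(model) == 0) stop("refusing to write a model with no reactions")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) vapply(x, function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (i in seq_along(model$compartments)) {
    w('      <compartment id="', esc(names(model$compartments)[i]),
      '" name="', esc(model$compartments[[i]]), '" constant="true"/>')
  }
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  mets <- model$metabolites
  for (i in seq_len(nrow(mets))) {
    extra <- ""
    if (!is.na(mets$formula[i])) {
      extra <- paste0(extra, ' fbc:chemicalFormula="', esc(mets$formula[i]), '"')
    }
    if (!is.na(mets$charge[i])) {
      extra <- paste0(extra, ' fbc:charge="', mets$charge[i], '"')
    }
    nm <- if (is.na(mets$name[i])) mets$id[i] else mets$name[i]
    w('      <species id="', esc(mets$id[i]), '" name="', esc(nm),
      '" compartment="', esc(mets$compartment[i]),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"', extra, '/>')
  }
  w('    </listOfSpecies>')
  rxns <- model$reactions
  bounds <- unique(c(rxns$lower_bound, rxns$upper_bound))
  bname <- stats::setNames(paste0("fb_", seq_along(bounds)), num(bounds))
  w('    <listOfParameters>')
  for (i in seq_along(bounds)) {
    w('      <parameter id="', bname[[num(bounds[i])]], '" value="',
      num(bounds[i]), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (j in seq_len(nrow(rxns))) {
    st <- reaction_stoichiometry(model, rxns$id[j])
    nm <- if (is.na(rxns$name[j])) rxns$id[j] else rxns$name[j]
    w('      <reaction id="', esc(rxns$id[j]), '" name="', esc(nm),
      '" reversible="', tolower(rxns$lower_bound[j] < 0), '" fast="false" ',
      'fbc:lowerFluxBound="', bname[[num(rxns$lower_bound[j])]],
      '" fbc:upperFluxBound="', bname[[num(rxns$upper_bound[j])]], '">')
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      w('        <listOfReactants>')
      for (k in seq_along(subs)) {
        w('          <speciesReference species="', esc(names(subs)[k]),
          '" stoichiometry="', num(-subs[k]), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (k in seq_along(prods)) {
        w('          <speciesReference species="', esc(names(prods)[k]),
          '" stoichiometry="', num(prods[k]), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    if (!is.na(rxns$gene_rule[j])) {
      w('        <fbc:geneProductAssociation>', esc(rxns$gene_rule[j]),
        '</fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (!is.na(model$objective_id)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="', esc(model$objective_id),
      '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
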
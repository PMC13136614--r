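SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
CHOTWIN_NS <- "https://chotwin.invalid/annotations"

#' Write a metabolic network as SBML Level 3 (FBC v2)
#'
#' Serialises species, reactions with stoichiometry, flux bounds (as shared
#' parameters referenced through `fbc:lowerFluxBound`/`upperFluxBound`) and
#' the active maximisation objective. The analyte map is stored in a small
#' model annotation so that a round trip is lossless.
#'
#' @param net a [metabolic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = net$id,
                               "fbc:strict" = "true")
  if (length(net$analyte_map)) {
    ann <- xml2::xml_add_child(model, "annotation")
    amap <- xml2::xml_add_child(ann, "analyteMap", xmlns = CHOTWIN_NS)
    for (r in names(net$analyte_map)) {
      xml2::xml_add_child(amap, "entry", reaction = r,
                          analyte = net$analyte_map[[r]])
    }
  }
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in unique(net$compartments)) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }
  specs <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in rownames(net$S)) {
    xml2::xml_add_child(specs, "species", id = m,
                        compartment = unname(net$compartments[m]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  fmt <- function(x) sprintf("%.17g", x)
  for (r in colnames(net$S)) {
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", r),
                        value = fmt(net$lb[r]), constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", r),
                        value = fmt(net$ub[r]), constant = "true")
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (r in colnames(net$S)) {
    rn <- xml2::xml_add_child(
      rxns, "reaction", id = r,
      reversible = tolower(as.character(net$lb[r] < 0)), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", r),
      "fbc:upperFluxBound" = paste0("ub_", r))
    col <- net$S[, r]
    rea <- names(col)[col < 0]
    pro <- names(col)[col > 0]
    if (length(rea)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in rea) {
        xml2::xml_add_child(lr, "speciesReference", species = m,
                            stoichiometry = fmt(-col[m]),
                            constant = "true")
      }
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in pro) {
        xml2::xml_add_child(lp, "speciesReference", species = m,
                            stoichiometry = fmt(col[m]), constant = "true")
      }
    }
  }
  objs <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = net$objective,
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a metabolic network from SBML Level 3 (FBC v2)
#'
#' Parses species/compartments, reaction stoichiometry, FBC flux bounds
#' (defaulting to (-1000, 1000) with a warning when absent) and the active
#' objective.
#'
#' @param path SBML file.
#' @return a [metabolic_network()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS, ct = CHOTWIN_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  model_id <- xml2::xml_attr(model, "id")
  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(sp, "id")
  comp <- stats::setNames(xml2::xml_attr(sp, "compartment"), mets)
  if (anyNA(comp) || any(comp == "")) {
    stop("species without compartment in ", path)
  }
  par_nodes <- xml2::xml_find_all(model,
                                  ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rids),
              dimnames = list(mets, rids))
  lb <- stats::setNames(numeric(length(rids)), rids)
  ub <- lb
  warned <- FALSE
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    for (sr in xml2::xml_find_all(node,
                                  "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      S[xml2::xml_attr(sr, "species"), i] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node,
                                  "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      S[xml2::xml_attr(sr, "species"), i] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) ||
        !lbid %in% names(par_vals) || !ubid %in% names(par_vals)) {
      if (!warned) {
        warning("reaction(s) without flux-bound annotations; using ",
                "defaults (-1000, 1000)")
        warned <- TRUE
      }
      lb[i] <- -1000; ub[i] <- 1000
    } else {
      lb[i] <- par_vals[[lbid]]
      ub[i] <- par_vals[[ubid]]
    }
  }
  obj_node <- xml2::xml_find_first(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj_node, "xml_missing")) {
    stop(sprintf("model '%s' has no objective", model_id))
  }
  objective <- xml2::xml_attr(obj_node, "reaction")
  entries <- xml2::xml_find_all(model, ".//ct:analyteMap/ct:entry", ns)
  amap <- NULL
  if (length(entries)) {
    amap <- stats::setNames(xml2::xml_attr(entries, "analyte"),
                            xml2::xml_attr(entries, "reaction"))
  }
  metabolic_network(id = model_id, S = S, lb = lb, ub = ub,
                    objective = objective, compartments = comp,
                    analyte_map = amap)
}
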
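#' Read a single-strain model from file
#'
#' Two dialects are supported. \code{toy_json} is this package's minimal
#' JSON form: \code{{"strain_id", "metabolites": [{"id","compartment",
#' "formula"}], "reactions": [{"id","stoich":{met: coef},"lb","ub",
#' "exchange","biomass"}]}}. \code{sbml_fbc} reads SBML Level 3 with the
#' flux-bounds (fbc) package; the biomass reaction is taken from the active
#' objective and exchange reactions are detected structurally.
#'
#' @param path file path.
#' @param dialect \code{"toy_json"} or \code{"sbml_fbc"}; default guessed
#'   from the file extension (.json vs .xml/.sbml).
#' @return a \code{\link{strain_model}}.
#' @export
load_strain_model <- function(path, dialect = c("auto", "toy_json", "sbml_fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "toy_json" else "sbml_fbc"
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(dialect,
         toy_json = read_toy_json(path),
         sbml_fbc = read_sbml_fbc(path))
}

read_toy_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("toy_json parse failure in '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("strain_id", "metabolites", "reactions"))
    if (is.null(doc[[f]])) stop("toy_json file '", path, "' lacks field '", f, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'")
    data.frame(id = m$id,
               name = if (is.null(m$name)) NA_character_ else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge))
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'")
    data.frame(id = r$id, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
               exchange = if (is.null(r$exchange)) NA else as.logical(r$exchange),
               biomass = if (is.null(r$biomass)) NA else as.logical(r$biomass))
  }))
  stoich <- lapply(doc$reactions, function(r)
    vapply(r$stoich, as.numeric, numeric(1)))
  names(stoich) <- rxns$id
  strain_model(doc$strain_id, mets, rxns, stoich)
}

#' Write a single-strain model to file
#'
#' @param model a \code{\link{strain_model}}.
#' @param path output path.
#' @param dialect \code{"toy_json"} or \code{"sbml_fbc"}.
#' @return \code{path}, invisibly.
#' @export
write_strain_model <- function(model, path,
                               dialect = c("toy_json", "sbml_fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "toy_json") write_toy_json(model, path)
  else write_sbml_fbc(model, path)
  invisible(path)
}

write_toy_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, compartment = m$compartment)
    if (!is.na(m$name)) out$name <- m$name
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    coef <- model$S[, r$id]
    coef <- coef[coef != 0]
    list(id = r$id, stoich = as.list(coef), lb = r$lb, ub = r$ub,
         exchange = r$exchange, biomass = r$biomass)
  })
  jsonlite::write_json(list(strain_id = model$strain_id,
                            metabolites = mets, reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## --- SBML Level 3 + fbc version 2 ------------------------------------------
## Minimal reader/writer pair covering the subset this package emits:
## compartments, species with chemical formulas, reactions with
## reactant/product stoichiometries, flux bounds through global parameters,
## and one active maximization objective marking the biomass reaction.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_num <- function(x) {
  if (is.infinite(x)) if (x > 0) "INF" else "-INF" else format(x, digits = 17)
}

parse_sbml_num <- function(s) {
  if (is.na(s)) return(NA_real_)
  if (s == "INF") return(Inf)
  if (s == "-INF") return(-Inf)
  as.numeric(s)
}

write_sbml_fbc <- function(model, path) {
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sid(model$strain_id),
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = sid(cp), constant = "true")
  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    nd <- xml2::xml_add_child(spl, "species", id = paste0("M_", sid(m$id)),
                              compartment = sid(m$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$name)) xml2::xml_set_attr(nd, "name", m$name)
    if (!is.na(m$formula)) xml2::xml_set_attr(nd, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(nd, "fbc:charge", as.character(m$charge))
  }
  prl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    xml2::xml_add_child(prl, "parameter", id = paste0("R_", sid(r$id), "_lb"),
                        value = sbml_num(r$lb), constant = "true")
    xml2::xml_add_child(prl, "parameter", id = paste0("R_", sid(r$id), "_ub"),
                        value = sbml_num(r$ub), constant = "true")
  }
  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    nd <- xml2::xml_add_child(rxl, "reaction", id = paste0("R_", sid(r$id)),
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("R_", sid(r$id), "_lb"),
                              "fbc:upperFluxBound" = paste0("R_", sid(r$id), "_ub"))
    coef <- model$S[, r$id]
    coef <- coef[coef != 0]
    if (any(coef < 0)) {
      lr <- xml2::xml_add_child(nd, "listOfReactants")
      for (m in names(coef)[coef < 0])
        xml2::xml_add_child(lr, "speciesReference", species = paste0("M_", sid(m)),
                            stoichiometry = format(-coef[[m]], digits = 17),
                            constant = "true")
    }
    if (any(coef > 0)) {
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      for (m in names(coef)[coef > 0])
        xml2::xml_add_child(lp, "speciesReference", species = paste0("M_", sid(m)),
                            stoichiometry = format(coef[[m]], digits = 17),
                            constant = "true")
    }
  }
  lob <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lob, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sid(biomass_reaction(model))),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("SBML file '", path, "' declares no species")
  attr_of <- function(node, name) {
    at <- xml2::xml_attrs(node)
    key <- names(at)[sub("^.*:", "", names(at)) == name]
    if (length(key)) at[[key[1L]]] else NA_character_
  }
  mets <- do.call(rbind, lapply(sp, function(s) {
    data.frame(id = strip(xml2::xml_attr(s, "id"), "M_"),
               name = xml2::xml_attr(s, "name"),
               compartment = xml2::xml_attr(s, "compartment"),
               formula = attr_of(s, "chemicalFormula"),
               charge = suppressWarnings(as.integer(attr_of(s, "charge"))))
  }))
  pars <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pv <- stats::setNames(vapply(pars, function(p) parse_sbml_num(xml2::xml_attr(p, "value")),
                               numeric(1)),
                        vapply(pars, function(p) xml2::xml_attr(p, "id"), character(1)))
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass_id <- if (inherits(fo, "xml_missing")) NA_character_ else
    strip(attr_of(fo, "reaction"), "R_")
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("SBML file '", path, "' declares no reactions")
  rxns <- list(); stoich <- list()
  for (nd in rx) {
    rid <- strip(xml2::xml_attr(nd, "id"), "R_")
    lbp <- attr_of(nd, "lowerFluxBound"); ubp <- attr_of(nd, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pv)) pv[[lbp]] else -OPEN_BOUND
    ub <- if (!is.na(ubp) && ubp %in% names(pv)) pv[[ubp]] else OPEN_BOUND
    coef <- numeric()
    for (sr in xml2::xml_find_all(nd, ".//*[local-name()='listOfReactants']/*"))
      coef[strip(xml2::xml_attr(sr, "species"), "M_")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(nd, ".//*[local-name()='listOfProducts']/*"))
      coef[strip(xml2::xml_attr(sr, "species"), "M_")] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = rid, lb = lb, ub = ub, exchange = NA,
      biomass = if (is.na(biomass_id)) NA else rid == biomass_id)
    stoich[[rid]] <- coef
  }
  model_id <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='model']"), "id")
  strain_model(model_id, mets, do.call(rbind, rxns), stoich)
}
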
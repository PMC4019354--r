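#' Load a genome-scale metabolic model from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`bigg-json`}{the BiGG database JSON schema (what
#'     `iAF1260.json` and the other published E. coli models ship as).}
#'   \item{`sbml-fbc`}{SBML Level 3 with the FBC package; chemical
#'     formulas are taken from `fbc:chemicalFormula` when present, else
#'     from a legacy `FORMULA: ...` line in the species notes.}
#'   \item{`native-json`}{this package's own dump format, written by
#'     [save_model()]; round-trips every field exactly.}
#' }
#'
#' @param path model file.
#' @param dialect one of `"bigg-json"`, `"sbml-fbc"`, `"native-json"`;
#'   `"auto"` guesses from the file extension and content.
#' @param biomass_reaction_id override the objective/biomass reaction.
#'   When the file does not designate one and no override is given, the
#'   error lists candidate ids containing "biomass"/"BIOMASS".
#' @return an [fba_model].
#' @export
load_model <- function(path, dialect = c("auto", "bigg-json", "sbml-fbc",
                                         "native-json"),
                       biomass_reaction_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      dialect <- "sbml-fbc"
    } else {
      head <- paste(readLines(path, n = 20L, warn = FALSE), collapse = "")
      dialect <- if (grepl("\"fbascreen_model\"", head, fixed = TRUE))
        "native-json" else "bigg-json"
    }
  }
  model <- switch(dialect,
                  "bigg-json" = read_bigg_json(path),
                  "sbml-fbc" = read_sbml_fbc(path),
                  "native-json" = read_native_json(path))
  if (!is.null(biomass_reaction_id)) {
    model$biomass_reaction_id <- biomass_reaction_id
  }
  if (is.na(model$biomass_reaction_id)) {
    cand <- model$reactions$id[grepl("biomass", model$reactions$id,
                                     ignore.case = TRUE)]
    stop("no biomass/objective reaction designated; candidates: ",
         if (length(cand)) paste(cand, collapse = ", ") else "<none found>")
  }
  validate_model(model)
  model
}

read_bigg_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions)) {
    stop("not a BiGG JSON model (missing metabolites/reactions): ", path)
  }
  g1 <- function(x, d = "") if (is.null(x)) d else x
  met <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = g1(m$name), formula = g1(m$formula),
    charge = as.integer(g1(m$charge, 0L)), compartment = g1(m$compartment),
    stringsAsFactors = FALSE)))
  ## BiGG files leave compartment implicit in the id suffix when absent
  noc <- !nzchar(met$compartment)
  met$compartment[noc] <- sub("^.*_([a-z]+)$", "\\1", met$id[noc])
  rxn <- do.call(rbind, lapply(j$reactions, function(r) data.frame(
    id = r$id, name = g1(r$name),
    lower_bound = as.numeric(g1(r$lower_bound, -1000)),
    upper_bound = as.numeric(g1(r$upper_bound, 1000)),
    gpr = g1(r$gene_reaction_rule), subsystem = g1(r$subsystem),
    stringsAsFactors = FALSE)))
  stoich <- lapply(j$reactions, function(r) {
    st <- unlist(r$metabolites)
    st[st != 0]
  })
  names(stoich) <- rxn$id
  genes <- if (!is.null(j$genes)) {
    vapply(j$genes, function(g) g$id, character(1))
  } else NULL
  bio <- NA_character_
  obj <- vapply(j$reactions, function(r) as.numeric(g1(r$objective_coefficient, 0)),
                numeric(1))
  if (any(obj != 0)) bio <- rxn$id[which(obj != 0)[1]]
  fba_model(met, rxn, stoich, genes = genes, biomass_reaction_id = bio)
}

#' Write a model as a native JSON dump
#'
#' The dump preserves every field of the container (ids, names,
#' formulas, charges, compartments, bounds, GPR strings, subsystems,
#' stoichiometries, gene list, biomass designation) in input order, so
#' `load_model(save_model(m), "native-json")` is an exact round trip and
#' identical models produce byte-identical files.
#'
#' @param model an [fba_model].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fba_model"))
  doc <- list(
    fbascreen_model = "1",
    biomass_reaction_id = model$biomass_reaction_id,
    genes = as.list(model$genes),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, ])),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- as.list(model$reactions[i, ])
      r$stoichiometry <- as.list(model$stoichiometry[[r$id]])
      r
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

read_native_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$fbascreen_model)) stop("not a native model dump: ", path)
  met <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = m$name, formula = m$formula,
    charge = as.integer(m$charge), compartment = m$compartment,
    stringsAsFactors = FALSE)))
  rxn <- do.call(rbind, lapply(j$reactions, function(r) data.frame(
    id = r$id, name = r$name, lower_bound = as.numeric(r$lower_bound),
    upper_bound = as.numeric(r$upper_bound), gpr = r$gpr,
    subsystem = r$subsystem, stringsAsFactors = FALSE)))
  stoich <- lapply(j$reactions, function(r) unlist(r$stoichiometry))
  names(stoich) <- rxn$id
  bio <- j$biomass_reaction_id
  fba_model(met, rxn, stoich, genes = unlist(j$genes),
            biomass_reaction_id = if (is.null(bio)) NA_character_ else bio)
}

read_sbml_fbc <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  attr1 <- function(node, a, d = "") {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) d else v
  }
  ## global flux-bound parameters
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp <- sp[xml2::xml_attr(sp, "boundaryCondition") %in% c(NA, "false")]
  met <- do.call(rbind, lapply(sp, function(nd) {
    fml <- xml2::xml_attr(nd, "chemicalFormula")   # fbc attr (namespaced)
    if (is.na(fml)) {
      notes <- xml2::xml_find_first(nd, ".//s:notes", ns)
      fml <- ""
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        mfm <- regmatches(txt, regexpr("FORMULA: ?[A-Za-z0-9]*", txt))
        if (length(mfm)) fml <- trimws(sub("FORMULA: ?", "", mfm))
      }
    }
    ch <- xml2::xml_attr(nd, "charge")
    data.frame(id = sbml_unprefix(attr1(nd, "id")),
               name = attr1(nd, "name"),
               formula = if (is.na(fml)) "" else fml,
               charge = if (is.na(ch)) 0L else as.integer(as.numeric(ch)),
               compartment = attr1(nd, "compartment"),
               stringsAsFactors = FALSE)
  }))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- list(); stoich <- list()
  for (nd in rx) {
    rid <- sbml_unprefix(attr1(nd, "id"))
    lbp <- xml2::xml_attr(nd, "lowerFluxBound")
    ubp <- xml2::xml_attr(nd, "upperFluxBound")
    rev <- identical(attr1(nd, "reversible", "true"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    reac <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      sbml_unprefix(xml2::xml_attr(reac, "species"))),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      sbml_unprefix(xml2::xml_attr(prod, "species"))))
    st <- tapply(st, names(st), sum)            # merge duplicated species refs
    st <- stats::setNames(as.numeric(st), names(st))
    gpa <- xml2::xml_find_first(nd, ".//fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else sbml_gpa_to_rule(gpa, ns)
    rows[[length(rows) + 1L]] <- data.frame(
      id = rid, name = attr1(nd, "name"), lower_bound = lb, upper_bound = ub,
      gpr = gpr, subsystem = "", stringsAsFactors = FALSE)
    stoich[[rid]] <- st[st != 0]
  }
  rxn <- do.call(rbind, rows)
  ## objective from fbc:listOfObjectives
  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  bio <- NA_character_
  if (!inherits(fo, "xml_missing")) {
    bio <- sbml_unprefix(xml2::xml_attr(fo, "reaction"))
  }
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- if (length(gp)) {
    unique(sbml_unprefix(ifelse(is.na(xml2::xml_attr(gp, "label")),
                                xml2::xml_attr(gp, "id"),
                                xml2::xml_attr(gp, "label"))))
  } else NULL
  m <- fba_model(met, rxn, stoich, genes = genes, biomass_reaction_id = bio)
  m
}

## SBML ids prefix species/reactions/genes with M_/R_/G_ by convention.
sbml_unprefix <- function(x) sub("^[MRG]_", "", x)

sbml_gpa_to_rule <- function(node, ns) {
  walk <- function(nd) {
    nm <- xml2::xml_name(nd)
    if (nm == "geneProductRef") {
      return(sbml_unprefix(xml2::xml_attr(nd, "geneProduct")))
    }
    kids <- xml2::xml_children(nd)
    parts <- vapply(kids, walk, character(1))
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else if (length(parts) == 1L) parts else
      paste0("(", paste(parts, collapse = " or "), ")")
  }
  kids <- xml2::xml_children(node)
  if (length(kids) == 0L) return("")
  walk(kids[[1]])
}

#' Write a mass-balance report as TSV
#'
#' @param model an [fba_model].
#' @param path output file.
#' @param ... passed to [check_mass_balance()].
#' @return the report data.frame, invisibly.
#' @export
write_mass_balance_report <- function(model, path, ...) {
  rep <- check_mass_balance(model, ...)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
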
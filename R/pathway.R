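#' Graft the heterologous 3HP / 1,3-PDO pathway onto a host model
#'
#' Adds the seven reactions that turn an E. coli host into a
#' 3-hydroxypropionic acid producer from glycerol:
#' \enumerate{
#'   \item glycerol dehydratase (dhaB/gdrAB): glycerol -> 3HPA + H2O
#'   \item 3HPA dehydrogenase (aldH): 3HPA + NAD+ + H2O -> 3HP + NADH + 2 H+
#'   \item 3HP transporter (proton symport, outward)
#'   \item 3HP exchange
#'   \item 1,3-PDO oxidoreductase (yqhD): 3HPA + NADPH + H+ -> 1,3-PDO + NADP+
#'   \item 1,3-PDO transporter (diffusion)
#'   \item 1,3-PDO exchange
#' }
#' All seven are irreversible in the written direction except the
#' 1,3-PDO diffusion step, which is reversible with an export-only
#' exchange.  The new metabolites (cytosolic 3HPA, 3HP, 1,3-PDO and
#' their extracellular forms) are created with real formulas; 3HP is
#' modeled as the -1 anion, matching the lactate convention of BiGG
#' models, with the symported proton carrying the charge.
#'
#' The pathway stoichiometry ships as a JSON data file
#' (`system.file("extdata", "pathway_3hp.json", package = "fbascreen")`)
#' so alternative stoichiometries can be swapped in without code
#' changes.
#'
#' The operation is deliberately not idempotent: applying it to a model
#' that already carries any of the seven reaction ids is an error.
#'
#' @param model host [fba_model]; must contain cytosolic glycerol,
#'   NAD(H), NADP(H), protons and water, and an extracellular
#'   compartment.
#' @param pathway_file optional path to an alternative pathway JSON.
#' @return the extended model.
#' @export
add_3hp_pathway <- function(model, pathway_file = NULL) {
  stopifnot(inherits(model, "fba_model"))
  if (is.null(pathway_file)) {
    pathway_file <- system.file("extdata", "pathway_3hp.json",
                                package = "fbascreen")
  }
  pw <- jsonlite::fromJSON(pathway_file, simplifyVector = FALSE)
  new_rxn_ids <- vapply(pw$reactions, function(r) r$id, "")
  dup <- intersect(new_rxn_ids, model$reactions$id)
  if (length(dup)) {
    stop("pathway reaction id(s) already present in model: ",
         paste(dup, collapse = ", "))
  }
  host_needs <- unique(unlist(lapply(pw$reactions, function(r)
    names(r$stoichiometry))))
  new_met_ids <- vapply(pw$metabolites, function(m) m$id, "")
  missing_host <- setdiff(setdiff(host_needs, new_met_ids),
                          model$metabolites$id)
  if (length(missing_host)) {
    stop("host model lacks metabolite(s) required by the pathway: ",
         paste(missing_host, collapse = ", "))
  }
  met_add <- do.call(rbind, lapply(pw$metabolites, function(m) data.frame(
    id = m$id, name = m$name, formula = m$formula,
    charge = as.integer(m$charge), compartment = m$compartment,
    stringsAsFactors = FALSE)))
  met_add <- met_add[!met_add$id %in% model$metabolites$id, , drop = FALSE]
  rxn_add <- do.call(rbind, lapply(pw$reactions, function(r) data.frame(
    id = r$id, name = r$name, lower_bound = as.numeric(r$lower_bound),
    upper_bound = as.numeric(r$upper_bound), gpr = r$gpr,
    subsystem = r$subsystem, stringsAsFactors = FALSE)))
  st_add <- lapply(pw$reactions, function(r) unlist(r$stoichiometry))
  names(st_add) <- rxn_add$id
  fba_model(rbind(model$metabolites, met_add),
            rbind(model$reactions, rxn_add),
            c(model$stoichiometry, st_add),
            genes = union(model$genes,
                          unlist(lapply(rxn_add$gpr, gpr_genes))),
            biomass_reaction_id = model$biomass_reaction_id)
}

#' Pseudo-genes carried by the heterologous pathway
#'
#' These identify the plasmid-borne production pathway itself (glycerol
#' dehydratase and its reactivase, and the aldehyde dehydrogenase); a
#' knockout screen excludes them by default, since deleting the product
#' pathway is never a design candidate.  The host gene `yqhD` behind the
#' 1,3-PDO oxidoreductase is *not* in this set — it is screenable.
#'
#' @return character vector of gene ids.
#' @export
pathway_pseudogenes <- function() c("dhaB", "gdrAB", "aldH")

#' Culture condition: glycerol-limited, oxygen-limited growth
#'
#' @param gur glycerol uptake rate, mmol/(gDC h); must be positive.
#' @param our oxygen uptake rate, mmol/(gDC h); 0 means anaerobic.
#' @param free_exchanges exchange reaction ids left fully open in both
#'   directions regardless of carbon content; defaults to the model's
#'   carbon-free inorganic exchanges plus CO2 (see [set_condition()]).
#' @return a `condition` object.
#' @export
condition <- function(gur = 15, our = 10, free_exchanges = NULL) {
  if (!is.numeric(gur) || gur <= 0) stop("GUR must be positive")
  if (!is.numeric(our) || our < 0) stop("OUR must be non-negative")
  structure(list(gur = gur, our = our, free_exchanges = free_exchanges),
            class = "condition")
}

#' Impose a glycerol/oxygen culture condition on a model
#'
#' Makes glycerol the sole carbon source: the glycerol exchange lower
#' bound is set to `-GUR` (the LP may take up less; yields are computed
#' on the uptake actually realized), the oxygen exchange lower bound to
#' `-OUR`, and every other carbon-containing exchange is closed to
#' uptake (lower bound 0) while remaining open for secretion.  Exchanges
#' of carbon-free species (phosphate, ammonium, water, protons, ...) and
#' CO2 are left free in both directions, following the convention that
#' small inorganics move freely across the membrane.
#'
#' @param model an [fba_model] with glycerol and oxygen exchanges
#'   (`EX_glyc_e`, `EX_o2_e`).
#' @param cond a [condition()].
#' @return the constrained model.
#' @export
set_condition <- function(model, cond) {
  stopifnot(inherits(model, "fba_model"), inherits(cond, "condition"))
  rxn <- model$reactions
  ex <- exchange_reactions(model)
  if (!"EX_glyc_e" %in% ex) stop("model has no glycerol exchange (EX_glyc_e)")
  if (!"EX_o2_e" %in% ex) stop("model has no oxygen exchange (EX_o2_e)")
  ex_met <- vapply(model$stoichiometry[ex], function(st) names(st)[1], "")
  nC <- carbon_counts(model, ex_met)
  free <- cond$free_exchanges
  if (is.null(free)) free <- c(ex[nC == 0], "EX_co2_e")
  for (i in seq_along(ex)) {
    rid <- ex[i]
    j <- match(rid, rxn$id)
    if (rid == "EX_glyc_e") {
      rxn$lower_bound[j] <- -cond$gur
    } else if (rid == "EX_o2_e") {
      rxn$lower_bound[j] <- -cond$our
      rxn$upper_bound[j] <- max(rxn$upper_bound[j], 0)
    } else if (rid %in% free) {
      ## leave as the model default (open both ways)
    } else if (nC[i] > 0) {
      rxn$lower_bound[j] <- 0            # no uptake of other carbon sources
    }
  }
  model$reactions <- rxn
  validate_model(model)
  model
}
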
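#' Construct a constraint-based metabolic model
#'
#' The container mirrors what every constraint-based toolbox carries: a
#' metabolite table (id, name, formula, charge, compartment), a reaction
#' table (id, name, bounds, GPR rule, subsystem), a stoichiometry list
#' keyed by reaction id, the gene universe, and the designated biomass
#' (objective) reaction.  All structural invariants are checked on
#' construction.
#'
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem`.
#' @param stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors over metabolite ids; negative = consumed.
#' @param genes character vector of gene ids; defaults to the union of
#'   all GPR genes.
#' @param biomass_reaction_id id of the biomass reaction, or `NA` for a
#'   model without one (it must be set before growth simulations).
#' @return object of class `fba_model`.
#' @export
fba_model <- function(metabolites, reactions, stoichiometry,
                      genes = NULL, biomass_reaction_id = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  need_m <- c("id", "name", "formula", "charge", "compartment")
  need_r <- c("id", "name", "lower_bound", "upper_bound", "gpr", "subsystem")
  if (!all(need_m %in% names(metabolites))) {
    stop("metabolites must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_r %in% names(reactions))) {
    stop("reactions must have columns: ", paste(need_r, collapse = ", "))
  }
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry[reactions$id],
         genes = genes,
         biomass_reaction_id = biomass_reaction_id),
    class = "fba_model")
  validate_model(model)
  model
}

#' Validate the structural invariants of a model
#'
#' Checks referential integrity (stoichiometry only over declared
#' metabolites, GPR genes in the gene universe, biomass reaction
#' present), bound sanity (`lb <= ub`), non-empty stoichiometries, and
#' the exchange convention (boundary reactions touch exactly one
#' extracellular metabolite).
#'
#' @param model an [fba_model].
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "fba_model"))
  rxn <- model$reactions
  met <- model$metabolites
  if (!setequal(names(model$stoichiometry), rxn$id) ||
      length(model$stoichiometry) != nrow(rxn)) {
    stop("stoichiometry list must have exactly one entry per reaction")
  }
  for (rid in rxn$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0L) stop("reaction '", rid, "' has empty stoichiometry")
    unknown <- setdiff(names(st), met$id)
    if (length(unknown)) {
      stop("reaction '", rid, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound in: ",
                        paste(bad, collapse = ", "))
  gpr_all <- unique(unlist(lapply(rxn$gpr, gpr_genes)))
  missing_genes <- setdiff(gpr_all, model$genes)
  if (length(missing_genes)) {
    stop("GPR genes absent from gene list: ",
         paste(missing_genes, collapse = ", "))
  }
  for (rid in exchange_reactions(model)) {
    st <- model$stoichiometry[[rid]]
    comp <- met$compartment[match(names(st), met$id)]
    if (length(st) != 1L || comp != "e") {
      stop("exchange reaction '", rid,
           "' must involve exactly one extracellular metabolite")
    }
  }
  if (!is.na(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rxn$id) {
    stop("biomass reaction '", model$biomass_reaction_id, "' not in model")
  }
  invisible(model)
}

#' @export
print.fba_model <- function(x, ...) {
  cat("Constraint-based metabolic model\n")
  cat("  metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " genes:", length(x$genes), "\n")
  cat("  biomass reaction:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Ids of exchange reactions
#'
#' An exchange reaction is a boundary pseudo-reaction with a single
#' metabolite; by the BiGG convention its id starts with `EX_`, its
#' metabolite lives in compartment `"e"`, and positive flux is secretion
#' while negative flux is uptake.
#'
#' @param model an [fba_model].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  rxn_ids <- model$reactions$id
  single <- vapply(model$stoichiometry, length, integer(1)) == 1L
  rxn_ids[single & grepl("^EX_", rxn_ids)]
}

#' Build the stoichiometric matrix S
#'
#' Rows are metabolites and columns reactions, both in model (input)
#' order so that repeated builds are bit-identical.  `S[i, j]` is the
#' signed coefficient of metabolite i in reaction j; steady state is
#' `S v = 0`.
#'
#' @param model an [fba_model].
#' @param sparse return a `Matrix::sparseMatrix` (default) or dense.
#' @return matrix with `dimnames = list(metabolite ids, reaction ids)`.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  stopifnot(inherits(model, "fba_model"))
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (jj in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[jj]]]
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep.int(jj, length(st)))
    x <- c(x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

## Reactions exempt from elemental balancing: boundary exchanges,
## demand/sink pseudo-reactions, and the lumped biomass drain.
balance_exempt <- function(model) {
  ex <- exchange_reactions(model)
  dm <- model$reactions$id[grepl("^(DM_|SK_|sink_)", model$reactions$id)]
  bio <- model$biomass_reaction_id
  unique(c(ex, dm, if (!is.na(bio)) bio))
}

#' Check elemental mass balance of every reaction
#'
#' For each non-exempt reaction, sums coefficient times atom count per
#' element; a conserving reaction sums to zero for every element.
#' Exchange, demand/sink and biomass reactions move matter across the
#' system boundary by design and are reported as skipped.  Charge
#' imbalance is reported alongside (element `"charge"`) but callers
#' typically treat it as advisory — published genome-scale models carry
#' known charge inconsistencies.
#'
#' @param model an [fba_model].
#' @param elements elements to check; default C, H, O, N, P, S.
#' @param charge also report net charge imbalance.
#' @return data.frame with columns `reaction_id`, `element`, `imbalance`,
#'   `status` (`"imbalanced"`, `"missing_formula"`, or `"skipped"`); rows
#'   only for problems and skips, so a fully balanced model yields only
#'   `"skipped"` rows.
#' @export
check_mass_balance <- function(model, elements = c("C", "H", "O", "N", "P", "S"),
                               charge = TRUE) {
  stopifnot(inherits(model, "fba_model"))
  met <- model$metabolites
  exempt <- balance_exempt(model)
  parsed <- lapply(met$formula, parse_formula)
  names(parsed) <- met$id
  has_formula <- nzchar(met$formula) & !is.na(met$formula)
  names(has_formula) <- met$id
  out <- list()
  add <- function(rid, el, imb, st) {
    out[[length(out) + 1L]] <<- data.frame(
      reaction_id = rid, element = el, imbalance = imb, status = st,
      stringsAsFactors = FALSE)
  }
  for (rid in model$reactions$id) {
    if (rid %in% exempt) { add(rid, NA_character_, NA_real_, "skipped"); next }
    st <- model$stoichiometry[[rid]]
    nofml <- names(st)[!has_formula[names(st)]]
    if (length(nofml)) {
      for (mid in nofml) add(rid, NA_character_, NA_real_, "missing_formula")
      next
    }
    for (el in elements) {
      cnt <- vapply(parsed[names(st)], function(f) {
        if (el %in% names(f)) as.numeric(f[[el]]) else 0
      }, numeric(1))
      imb <- sum(unname(st) * cnt)
      if (abs(imb) > 1e-6) add(rid, el, imb, "imbalanced")
    }
    if (charge) {
      q <- met$charge[match(names(st), met$id)]
      if (!anyNA(q)) {
        imb <- sum(unname(st) * q)
        if (abs(imb) > 1e-6) add(rid, "charge", imb, "imbalanced")
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(reaction_id = character(0), element = character(0),
               imbalance = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
}

#' Net carbon drained by the biomass reaction
#'
#' Carbon consumed minus carbon returned by the biomass equation, in
#' mmol C per gram dry cell.  Growth at rate mu (1/h) therefore fixes
#' `mu * net_biomass_carbon(model)` mmol C/(gDC h) of carbon in new
#' biomass, which is the numerator of the biomass C-mol yield.
#' Cofactor pairs that cycle through the equation (ATP/ADP, NAD(P)/H,
#' CoA/acetyl-CoA) cancel automatically because only net carbon counts.
#'
#' @param model an [fba_model] with a biomass reaction.
#' @return positive scalar, mmol C per gDC.
#' @export
net_biomass_carbon <- function(model) {
  stopifnot(inherits(model, "fba_model"))
  bio <- model$biomass_reaction_id
  if (is.na(bio)) stop("model has no biomass reaction")
  st <- model$stoichiometry[[bio]]
  met <- model$metabolites
  idx <- match(names(st), met$id)
  no_f <- names(st)[!nzchar(met$formula[idx]) | is.na(met$formula[idx])]
  if (length(no_f)) {
    stop("biomass participant(s) lack a formula: ", paste(no_f, collapse = ", "))
  }
  carb <- vapply(met$formula[idx], element_count, integer(1), element = "C",
                 USE.NAMES = FALSE)
  -sum(unname(st) * carb)        # consumed (negative coeff) minus produced
}
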
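#' Reactions disabled by a gene deletion
#'
#' A reaction is disabled when its GPR rule evaluates to `FALSE` with
#' the deleted genes absent; reactions with empty rules are never
#' disabled.
#'
#' @param model an [fba_model].
#' @param genes character vector of deleted gene ids.
#' @return character vector of disabled reaction ids.
#' @export
disabled_reactions <- function(model, genes) {
  stopifnot(inherits(model, "fba_model"))
  if (length(genes) == 0L) return(character(0))
  ## only reactions mentioning a deleted gene can change state
  touches <- vapply(model$reactions$gpr, function(g)
    any(gpr_genes(g) %in% genes), logical(1), USE.NAMES = FALSE)
  cand <- which(touches)
  off <- !vapply(model$reactions$gpr[cand], evaluate_gpr, logical(1),
                 deleted = genes, USE.NAMES = FALSE)
  model$reactions$id[cand[off]]
}

#' Apply a gene knockout to a model
#'
#' Implements the standard GPR-mediated deletion: every reaction whose
#' rule loses enzymatic support has both flux bounds set to zero; all
#' other reactions are untouched.  The input model is not modified.
#'
#' @param model an [fba_model].
#' @param genes gene ids to delete; every id must exist in
#'   `model$genes` (unknown ids raise an error listing near-matches).
#' @return a new model with the deletion applied.
#' @export
apply_knockout <- function(model, genes) {
  stopifnot(inherits(model, "fba_model"))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    near <- unlist(lapply(unknown, function(g) {
      d <- utils::adist(g, model$genes, ignore.case = TRUE)
      model$genes[d <= 2]
    }))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         if (length(near)) paste0(" (did you mean: ",
                                  paste(unique(near), collapse = ", "), "?)"))
  }
  off <- disabled_reactions(model, genes)
  if (length(off)) {
    i <- match(off, model$reactions$id)
    model$reactions$lower_bound[i] <- 0
    model$reactions$upper_bound[i] <- 0
  }
  model
}

screen_record <- function(genes, sol, mu_wt, model, substrate = "EX_glyc_e",
                          product = "EX_3hp_e") {
  off <- disabled_reactions(model, genes)
  if (sol$status != "optimal" || is.na(sol$primary_value) ||
      sol$primary_value < 1e-9) {
    mu <- 0; p <- 0; y <- 0
  } else {
    mu <- sol$primary_value
    p <- max(get_flux(sol, product), 0)
    upt <- -get_flux(sol, substrate)
    y <- if (upt > 1e-9) {
      nC <- carbon_counts(model,
                          c(names(model$stoichiometry[[product]])[1],
                            names(model$stoichiometry[[substrate]])[1]))
      100 * p * nC[[1]] / (upt * nC[[2]])
    } else 0
  }
  data.frame(gene_1 = if (length(genes) >= 1L) genes[1] else NA_character_,
             gene_2 = if (length(genes) >= 2L) genes[2] else NA_character_,
             growth_rate = mu,
             relative_growth_pct = if (mu_wt > 0) 100 * mu / mu_wt else NA_real_,
             threehp_flux = p,
             threehp_yield_cmol_pct = y,
             n_reactions_disabled = length(off),
             stringsAsFactors = FALSE)
}

#' Single-gene knockout screen
#'
#' Deletes each gene in turn, re-solves the two-stage (growth, then
#' product) LP, and records growth rate, product flux and carbon-molar
#' product yield.  Deletions that make growth infeasible are recorded
#' as lethal (growth 0, yield 0), not errors.
#'
#' @param model an [fba_model], already under its culture condition.
#' @param genes genes to screen; defaults to all model genes except the
#'   heterologous pathway pseudo-genes ([pathway_pseudogenes()]).
#' @param primary stage-1 objective (default the biomass reaction).
#' @param secondary stage-2 objective (default `"EX_3hp_e"`).
#' @param substrate substrate exchange for the yield basis.
#' @return data.frame, one row per gene, columns `gene_1`, `gene_2`
#'   (`NA`), `growth_rate`, `relative_growth_pct`, `threehp_flux`,
#'   `threehp_yield_cmol_pct`, `n_reactions_disabled`.
#' @export
single_knockout_screen <- function(model, genes = NULL, primary = NULL,
                                   secondary = "EX_3hp_e",
                                   substrate = "EX_glyc_e") {
  stopifnot(inherits(model, "fba_model"))
  if (is.null(primary)) primary <- model$biomass_reaction_id
  if (is.null(genes)) genes <- setdiff(model$genes, pathway_pseudogenes())
  wt <- solve_fba(model, objective = primary)
  if (wt$status != "optimal") stop("wild-type model does not solve: ",
                                   wt$status)
  mu_wt <- wt$objective_value
  if (length(genes) == 0L) return(empty_screen_table())
  rows <- lapply(genes, function(g) {
    km <- apply_knockout(model, g)
    sol <- solve_lexicographic(km, primary = primary, secondary = secondary)
    screen_record(g, sol, mu_wt, model, substrate, secondary)
  })
  do.call(rbind, rows)
}

empty_screen_table <- function() {
  data.frame(gene_1 = character(0), gene_2 = character(0),
             growth_rate = numeric(0), relative_growth_pct = numeric(0),
             threehp_flux = numeric(0), threehp_yield_cmol_pct = numeric(0),
             n_reactions_disabled = integer(0), stringsAsFactors = FALSE)
}

#' Double-gene knockout screen
#'
#' Evaluates every unordered gene pair by two-stage FBA and ranks the
#' results by product yield (then relative growth, then gene ids, so
#' the ranking is deterministic).  Pairs whose GPR-disabled reaction
#' sets coincide are solved once and share the result — on
#' genome-scale models this equivalence-class deduplication removes the
#' large fraction of pairs that hit the same reactions through
#' isozymes or shared complexes.
#'
#' @inheritParams single_knockout_screen
#' @param top_k rows to return (the full ranked table is available via
#'   `attr(result, "full_table")`); `Inf` returns everything.
#' @param progress_every log progress to `message()` every this many
#'   LP solves; 0 disables logging.
#' @return ranked data.frame as in [single_knockout_screen()], with
#'   both `gene_1` and `gene_2` set.
#' @export
double_knockout_screen <- function(model, genes = NULL, primary = NULL,
                                   secondary = "EX_3hp_e",
                                   substrate = "EX_glyc_e",
                                   top_k = Inf, progress_every = 0) {
  stopifnot(inherits(model, "fba_model"))
  if (is.null(primary)) primary <- model$biomass_reaction_id
  if (is.null(genes)) genes <- setdiff(model$genes, pathway_pseudogenes())
  genes <- sort(unique(genes))
  wt <- solve_fba(model, objective = primary)
  if (wt$status != "optimal") stop("wild-type model does not solve: ",
                                   wt$status)
  mu_wt <- wt$objective_value
  if (length(genes) < 2L) {
    res <- empty_screen_table()
    attr(res, "full_table") <- res
    return(res)
  }
  pairs <- utils::combn(genes, 2L, simplify = FALSE)
  ## deduplicate on the disabled-reaction set: identical sets give
  ## identical LPs, so solve each class once
  keys <- vapply(pairs, function(p)
    paste(sort(disabled_reactions(model, p)), collapse = "|"), "")
  classes <- split(seq_along(pairs), keys)
  cache <- new.env(parent = emptyenv())
  nsolve <- 0L
  rows <- vector("list", length(pairs))
  for (key in names(classes)) {
    idx <- classes[[key]]
    p0 <- pairs[[idx[1]]]
    km <- apply_knockout(model, p0)
    sol <- solve_lexicographic(km, primary = primary, secondary = secondary)
    nsolve <- nsolve + 1L
    if (progress_every > 0 && nsolve %% progress_every == 0L) {
      message("double knockout screen: ", nsolve, " LP classes of ",
              length(classes), " solved")
    }
    for (i in idx) {
      rows[[i]] <- screen_record(pairs[[i]], sol, mu_wt, model,
                                 substrate, secondary)
    }
  }
  res <- do.call(rbind, rows)
  ord <- order(-res$threehp_yield_cmol_pct, -res$relative_growth_pct,
               res$gene_1, res$gene_2, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  out <- utils::head(res, if (is.finite(top_k)) top_k else nrow(res))
  attr(out, "full_table") <- res
  out
}
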
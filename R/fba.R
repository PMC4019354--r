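#' Flux balance analysis
#'
#' Solves the canonical FBA linear program
#' \deqn{\max_v c^\top v \quad \text{s.t.}\quad S v = 0,\;
#'       v_{min} \le v \le v_{max}}
#' where `c` selects a single objective reaction.  The LP is solved by
#' the package's bounded-variable simplex ([simplex_bounded]), which
#' returns a basic solution, so repeated solves of the same model are
#' deterministic.  The optimal objective value is unique even when the
#' flux vector is degenerate.
#'
#' @param model an [fba_model].
#' @param objective reaction id to optimize; defaults to the model's
#'   biomass reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @return an object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value`,
#'   `objective_id`, `sense`, and `fluxes` (named numeric over all
#'   reaction ids; `NA` unless optimal).
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "fba_model"))
  if (is.null(objective)) objective <- model$biomass_reaction_id
  rxn <- model$reactions
  if (!objective %in% rxn$id) stop("objective reaction not in model: ", objective)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  cc <- as.numeric(rxn$id == objective)
  res <- simplex_bounded(cc, S, rep(0, nrow(S)),
                         rxn$lower_bound, rxn$upper_bound, sense = sense)
  fluxes <- rep(NA_real_, nrow(rxn))
  names(fluxes) <- rxn$id
  if (res$status == "optimal") {
    fluxes[] <- res$x
    resid <- max(abs(S %*% res$x))
    if (resid > 1e-6) {
      stop("solver returned a point violating S v = 0 (|resid| = ",
           format(resid), ")")
    }
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal")
                   res$objective else NA_real_,
                 objective_id = objective,
                 sense = sense,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution [", x$status, "]  ", x$sense, " ", x$objective_id,
      " = ", format(x$objective_value, digits = 8), "\n", sep = "")
  if (!is.null(x$primary_id)) {
    cat("  primary ", x$primary_id, " fixed at ",
        format(x$primary_value, digits = 8), "\n", sep = "")
  }
  invisible(x)
}

#' Two-stage (lexicographic) flux balance analysis
#'
#' Stage 1 maximizes the primary objective (typically biomass) to obtain
#' its optimum `z*`; stage 2 maximizes the secondary objective (typically
#' product export) subject to the primary flux being held at `z*`.  This
#' removes the degeneracy that makes a product flux "undetermined" at
#' the growth optimum: the value reported for the secondary objective is
#' the largest compatible with maximal growth.
#'
#' The stage-2 pin uses a relative relaxation,
#' `v_primary >= z* (1 - 1e-6)`, rather than an equality — exact fixing
#' at a floating-point optimum is numerically brittle.
#'
#' @param model an [fba_model].
#' @param primary stage-1 objective reaction id (default biomass).
#' @param secondary stage-2 objective reaction id.
#' @param fix_tol relative relaxation of the stage-2 pin.
#' @return a `flux_solution` for the stage-2 LP, with extra fields
#'   `primary_id` and `primary_value` (the stage-1 optimum).  Stage-1
#'   infeasibility propagates as the returned status.
#' @export
solve_lexicographic <- function(model, primary = NULL, secondary,
                                fix_tol = 1e-6) {
  stopifnot(inherits(model, "fba_model"))
  if (is.null(primary)) primary <- model$biomass_reaction_id
  if (!secondary %in% model$reactions$id) {
    stop("secondary objective not in model: ", secondary)
  }
  s1 <- solve_fba(model, objective = primary, sense = "max")
  if (s1$status != "optimal") {
    s1$primary_id <- primary
    s1$primary_value <- NA_real_
    return(s1)
  }
  z <- s1$objective_value
  m2 <- model
  i <- match(primary, m2$reactions$id)
  floor_z <- if (z >= 0) z * (1 - fix_tol) else z * (1 + fix_tol)
  m2$reactions$lower_bound[i] <- max(m2$reactions$lower_bound[i], floor_z)
  s2 <- solve_fba(m2, objective = secondary, sense = "max")
  s2$primary_id <- primary
  s2$primary_value <- z
  s2
}

#' Read one flux from a solution
#'
#' @param solution a `flux_solution`.
#' @param reaction_id reaction id.
#' @return numeric flux (signed).
#' @export
get_flux <- function(solution, reaction_id) {
  stopifnot(inherits(solution, "flux_solution"))
  if (!reaction_id %in% names(solution$fluxes)) {
    stop("unknown reaction id: ", reaction_id)
  }
  unname(solution$fluxes[reaction_id])
}
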
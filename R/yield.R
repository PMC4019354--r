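#' Carbon-molar yield
#'
#' `100 * (product_flux * product_carbons) / (substrate_flux *
#' substrate_carbons)` — the percentage of consumed substrate carbon
#' that ends up in the product.
#'
#' @param product_flux non-negative product secretion flux,
#'   mmol/(gDC h).
#' @param product_carbons carbon atoms per product molecule.
#' @param substrate_flux positive substrate consumption flux (a
#'   magnitude, not a signed exchange flux).
#' @param substrate_carbons carbon atoms per substrate molecule.
#' @return yield in C-mol%.
#' @export
cmol_yield <- function(product_flux, product_carbons,
                       substrate_flux, substrate_carbons) {
  if (any(substrate_flux <= 0)) stop("substrate_flux must be positive")
  if (any(product_flux < 0)) stop("product_flux must be non-negative")
  100 * (product_flux * product_carbons) / (substrate_flux * substrate_carbons)
}

#' Growth rate relative to wild-type
#'
#' @param mu_ko knockout growth rate, 1/h.
#' @param mu_wt wild-type growth rate, 1/h; must be positive.
#' @return percentage, `100 * mu_ko / mu_wt`.
#' @export
relative_growth <- function(mu_ko, mu_wt) {
  if (any(mu_wt <= 0)) stop("wild-type growth rate must be positive")
  100 * mu_ko / mu_wt
}

## default product panel for the yield table (exchange id, label)
yield_products <- function() {
  c("3hp" = "EX_3hp_e", "13pdo" = "EX_13pdo_e", "acetate" = "EX_ac_e",
    "succinate" = "EX_succ_e", "lactate" = "EX_lac__D_e",
    "ethanol" = "EX_etoh_e", "formate" = "EX_for_e", "co2" = "EX_co2_e")
}

#' Carbon-molar yield table for an optimal flux solution
#'
#' Computes the C-mol% yields of the standard product panel (3HP,
#' 1,3-PDO, acetate, succinate, lactate, ethanol, formate, CO2) and of
#' biomass, on the glycerol actually consumed in the solution (not the
#' uptake bound).  Product carbon numbers come from metabolite
#' formulas; biomass carbon from [net_biomass_carbon()].  Secretion
#' fluxes below `flux_zero` are reported as exact zeros to suppress
#' solver noise.
#'
#' @param solution an optimal `flux_solution`.
#' @param model the model it was solved on.
#' @param substrate substrate exchange id (default `"EX_glyc_e"`).
#' @param products named character vector of product exchange ids;
#'   entries absent from the model are reported as `NA`.
#' @param flux_zero fluxes with magnitude below this are treated as 0.
#' @return object of class `yield_report`: list with
#'   `consumed_glycerol_flux`, `growth_rate`, `biomass_yield`,
#'   `product_yields` (named numeric, C-mol%), and `carbon_closure`
#'   (sum of all yields incl. CO2 and biomass; ~100 when the exchange
#'   panel covers every secreted carbon species).
#' @export
yield_table <- function(solution, model, substrate = "EX_glyc_e",
                        products = yield_products(), flux_zero = 1e-7) {
  stopifnot(inherits(solution, "flux_solution"), inherits(model, "fba_model"))
  if (solution$status != "optimal") stop("solution is not optimal")
  upt <- -get_flux(solution, substrate)
  if (upt <= flux_zero) stop("no substrate consumed; yields are undefined")
  sub_met <- names(model$stoichiometry[[substrate]])[1]
  nC_sub <- carbon_counts(model, sub_met)[[1]]
  pm <- names(products)
  yields <- stats::setNames(rep(NA_real_, length(products)), pm)
  for (i in seq_along(products)) {
    ex <- products[[i]]
    if (!ex %in% model$reactions$id) next
    fl <- get_flux(solution, ex)
    if (abs(fl) < flux_zero) fl <- 0
    fl <- max(fl, 0)                         # secreted only
    met <- names(model$stoichiometry[[ex]])[1]
    yields[i] <- cmol_yield(fl, carbon_counts(model, met)[[1]], upt, nC_sub)
  }
  mu <- if (!is.na(model$biomass_reaction_id))
    get_flux(solution, model$biomass_reaction_id) else NA_real_
  bio_yield <- if (!is.na(mu)) {
    100 * mu * net_biomass_carbon(model) / (upt * nC_sub)
  } else NA_real_
  structure(list(consumed_glycerol_flux = upt,
                 growth_rate = mu,
                 biomass_yield = bio_yield,
                 product_yields = yields,
                 carbon_closure = sum(yields, na.rm = TRUE) +
                   if (is.na(bio_yield)) 0 else bio_yield),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Yield report (basis: consumed glycerol ",
      format(x$consumed_glycerol_flux, digits = 6), " mmol/(gDC h))\n",
      sep = "")
  cat(sprintf("  growth rate   %8.4f 1/h\n", x$growth_rate))
  cat(sprintf("  biomass       %8.1f C-mol%%\n", x$biomass_yield))
  ## CO2 belongs in the machine-readable table but not the summary
  show <- x$product_yields[setdiff(names(x$product_yields), "co2")]
  for (nm in names(show)) {
    if (!is.na(show[[nm]])) {
      cat(sprintf("  %-12s %8.1f C-mol%%\n", nm, show[[nm]]))
    }
  }
  cat(sprintf("  carbon closure (incl. CO2): %.1f C-mol%%\n",
              x$carbon_closure))
  invisible(x)
}

#' Normalize fluxes to percent of glycerol uptake
#'
#' The convention of published flux maps: each flux is expressed as a
#' signed percentage of the glycerol uptake rate, so the substrate
#' enters at 100%.
#'
#' @param solution an optimal `flux_solution`.
#' @param reaction_subset reaction ids to report; unknown ids error.
#' @param substrate substrate exchange id.
#' @return named numeric vector, percent of glycerol uptake (signed).
#' @export
normalize_flux_map <- function(solution, reaction_subset,
                               substrate = "EX_glyc_e") {
  stopifnot(inherits(solution, "flux_solution"))
  unknown <- setdiff(reaction_subset, names(solution$fluxes))
  if (length(unknown)) stop("unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  upt <- -get_flux(solution, substrate)
  if (upt <= 0) stop("no substrate uptake; cannot normalize")
  100 * solution$fluxes[reaction_subset] / upt
}

#' Growth and product yield across oxygen uptake rates
#'
#' Re-imposes the condition at each OUR in `our_values` (GUR held
#' fixed) and runs the two-stage LP, giving the aerobiosis profile of
#' growth and product yield — the sweep behind phenotype-phase-plane
#' style analyses of the OUR/GUR ratio.
#'
#' @param model model *before* condition setting, or with any condition
#'   (it is overwritten per row).
#' @param gur glycerol uptake rate.
#' @param our_values vector of oxygen uptake rates (>= 0).
#' @param primary stage-1 objective (default biomass).
#' @param secondary stage-2 objective (default `"EX_3hp_e"`).
#' @return data.frame with columns `our`, `growth_rate`,
#'   `threehp_flux`, `threehp_yield_cmol_pct`, rows in input order.
#' @export
our_sweep <- function(model, gur = 15, our_values = seq(0, 20, by = 2.5),
                      primary = NULL, secondary = "EX_3hp_e") {
  stopifnot(inherits(model, "fba_model"))
  if (any(our_values < 0)) stop("OUR values must be non-negative")
  if (is.null(primary)) primary <- model$biomass_reaction_id
  rows <- lapply(our_values, function(o) {
    mc <- set_condition(model, condition(gur, o))
    sol <- solve_lexicographic(mc, primary = primary, secondary = secondary)
    if (sol$status != "optimal") {
      return(data.frame(our = o, growth_rate = 0, threehp_flux = 0,
                        threehp_yield_cmol_pct = 0))
    }
    upt <- -get_flux(sol, "EX_glyc_e")
    p <- max(get_flux(sol, secondary), 0)
    y <- if (upt > 1e-9) {
      pm <- names(mc$stoichiometry[[secondary]])[1]
      sm <- names(mc$stoichiometry[["EX_glyc_e"]])[1]
      nC <- carbon_counts(mc, c(pm, sm))
      cmol_yield(p, nC[[1]], upt, nC[[2]])
    } else 0
    data.frame(our = o, growth_rate = sol$primary_value,
               threehp_flux = p, threehp_yield_cmol_pct = y)
  })
  do.call(rbind, rows)
}
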
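#' Configuration for a full simulation run
#'
#' A flat configuration mirroring the stage functions' arguments.
#' `model_path = "core"` uses the built-in reduced central-carbon
#' model instead of reading a file.
#'
#' @param model_path model file, or `"core"` for [build_core_model()].
#' @param dialect model dialect for [load_model()].
#' @param gur,our culture condition, mmol/(gDC h).
#' @param add_pathway graft the 3HP/1,3-PDO pathway before running.
#' @param knockouts gene ids to delete before solving.
#' @param objective primary objective reaction (default: model biomass).
#' @param secondary secondary objective for the lexicographic stage.
#' @param screen_order 0 = no screen, 1 = single, 2 = double knockouts.
#' @param gene_subset genes to screen (default: all non-pathway genes).
#' @param top_k rows reported from a double screen.
#' @param output_dir directory for `fluxes.tsv`, `yields.json`,
#'   `screen.tsv` and `run.log`.
#' @param seed reserved for future stochastic stages; the current
#'   pipeline is fully deterministic and ignores it.
#' @return a `run_config` list.
#' @export
run_config <- function(model_path = "core", dialect = "auto",
                       gur = 15, our = 10, add_pathway = TRUE,
                       knockouts = character(0), objective = NULL,
                       secondary = "EX_3hp_e", screen_order = 0,
                       gene_subset = NULL, top_k = 20,
                       output_dir = ".", seed = 1L) {
  if (!screen_order %in% 0:2) stop("screen_order must be 0, 1 or 2")
  structure(list(model_path = model_path, dialect = dialect, gur = gur,
                 our = our, add_pathway = add_pathway, knockouts = knockouts,
                 objective = objective, secondary = secondary,
                 screen_order = screen_order, gene_subset = gene_subset,
                 top_k = top_k, output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Run the full load / extend / condition / knockout / solve / report
#' pipeline
#'
#' Chains every stage of the workflow and writes `fluxes.tsv` (one row
#' per reaction: id, flux, subsystem), `yields.json` (the yield
#' report), optionally `screen.tsv` (the ranked knockout table), and
#' `run.log` (stage-by-stage status).  Stage failures propagate as
#' errors naming the stage; no partial output files are left behind on
#' failure (writes go to the output directory only after all
#' computation succeeds).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the model, solution, yield report and
#'   (if requested) screen table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- stage("load", {
    if (identical(config$model_path, "core")) build_core_model()
    else load_model(config$model_path, config$dialect)
  })
  logit("loaded model: ", nrow(model$reactions), " reactions, ",
        nrow(model$metabolites), " metabolites")
  if (config$add_pathway) {
    model <- stage("extend", add_3hp_pathway(model))
    logit("grafted 3HP/1,3-PDO pathway (7 reactions)")
  }
  model <- stage("condition",
                 set_condition(model, condition(config$gur, config$our)))
  logit("condition: GUR = ", config$gur, ", OUR = ", config$our,
        " mmol/(gDC h)")
  kmodel <- model
  if (length(config$knockouts)) {
    kmodel <- stage("knockout", apply_knockout(model, config$knockouts))
    logit("applied knockout: ", paste(config$knockouts, collapse = ", "))
  }
  objective <- config$objective
  if (is.null(objective)) objective <- kmodel$biomass_reaction_id
  sol <- stage("solve",
               solve_lexicographic(kmodel, primary = objective,
                                   secondary = config$secondary))
  if (sol$status != "optimal") {
    stop("pipeline stage 'solve' failed: LP status ", sol$status,
         call. = FALSE)
  }
  logit("lexicographic solve: ", objective, " = ",
        format(sol$primary_value, digits = 8), ", ", config$secondary,
        " = ", format(sol$objective_value, digits = 8),
        " (feasibility tol 1e-9, reporting tol 1e-6)")
  yr <- stage("report", yield_table(sol, kmodel))
  screen <- NULL
  if (config$screen_order > 0) {
    screen <- stage("screen", {
      if (config$screen_order == 1L) {
        single_knockout_screen(model, genes = config$gene_subset,
                               primary = objective,
                               secondary = config$secondary)
      } else {
        double_knockout_screen(model, genes = config$gene_subset,
                               primary = objective,
                               secondary = config$secondary,
                               top_k = config$top_k)
      }
    })
    logit("knockout screen (order ", config$screen_order, "): ",
          nrow(screen), " records reported")
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  write_flux_tsv(sol, kmodel, out("fluxes.tsv"))
  write_yields_json(yr, out("yields.json"))
  if (!is.null(screen)) {
    utils::write.table(screen, out("screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, out("run.log"))
  invisible(list(model = kmodel, solution = sol, yields = yr,
                 screen = screen))
}

#' Write a flux distribution as TSV
#'
#' Columns `reaction_id`, `flux`, `subsystem`; fluxes with magnitude
#' below `flux_zero` are written as 0 to suppress solver noise.
#'
#' @param solution a `flux_solution`.
#' @param model the model it was solved on.
#' @param path output file.
#' @param flux_zero zero-reporting threshold.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(solution, model, path, flux_zero = 1e-7) {
  fl <- solution$fluxes
  fl[abs(fl) < flux_zero] <- 0
  df <- data.frame(reaction_id = model$reactions$id,
                   flux = unname(fl[model$reactions$id]),
                   subsystem = model$reactions$subsystem,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a yield report as JSON
#'
#' @param report a `yield_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_yields_json <- function(report, path) {
  stopifnot(inherits(report, "yield_report"))
  jsonlite::write_json(
    list(consumed_glycerol_flux = report$consumed_glycerol_flux,
         growth_rate = report$growth_rate,
         biomass_yield_cmol_pct = report$biomass_yield,
         product_yields_cmol_pct = as.list(report$product_yields),
         carbon_closure_cmol_pct = report$carbon_closure),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
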
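# Shared fixtures: models are built once per test run and reused.

core_m <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_core_model()
    m
  }
})

# core host + 3HP pathway + microaerobic glycerol condition (GUR 15, OUR 10)
prod_m <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- set_condition(add_3hp_pathway(build_core_model()),
                          condition(15, 10))
    }
    m
  }
})

screen_genes <- c("tpiA", "zwf", "pgi", "edd", "gldA", "fsaB", "yqhD", "mgsA")

# Independent LP oracle: formulates max c'v s.t. S v = 0, lb <= v <= ub
# directly from the model's stoichiometry list (not via solve_fba) and
# solves with scipy.optimize.linprog (HiGHS) in a python subprocess.
scipy_fba_objective <- function(model, objective, sense = "max") {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, length(met_ids), length(rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[j]]]
    S[match(names(st), met_ids), j] <- unname(st)
  }
  cc <- as.numeric(rxn_ids == objective)
  inp <- jsonlite::toJSON(
    list(c = cc, A = S, lb = model$reactions$lower_bound,
         ub = model$reactions$upper_bound, sense = sense),
    digits = NA, matrix = "rowmajor")
  fin <- tempfile(fileext = ".json")
  writeLines(inp, fin)
  script <- "
import json, sys, numpy as np
from scipy.optimize import linprog
d = json.load(open(sys.argv[1]))
c = np.array(d['c'], float)
A = np.array(d['A'], float)
sgn = -1.0 if d['sense'][0] == 'max' else 1.0
r = linprog(sgn * c, A_eq=A, b_eq=np.zeros(A.shape[0]),
            bounds=list(zip(d['lb'], d['ub'])), method='highs')
print(json.dumps({'status': int(r.status),
                  'obj': (sgn * r.fun) if r.status == 0 else None}))
"
  out <- system2("python", c("-c", shQuote(script), fin), stdout = TRUE)
  res <- jsonlite::fromJSON(out)
  if (res$status != 0) stop("scipy oracle LP not optimal (status ",
                            res$status, ")")
  res$obj
}

# Where a locally provided genome-scale iAF1260 model would live; the
# package ships none (the published model must be fetched once by the
# user from the BiGG database).
iaf1260_path <- function() {
  cand <- c(getOption("fbascreen.iaf1260", ""),
            file.path(testthat::test_path(), "iAF1260.json"),
            "iAF1260.json",
            file.path(tools::R_user_dir("fbascreen", "cache"),
                      "iAF1260.json"))
  cand <- cand[nzchar(cand)]
  hit <- cand[file.exists(cand)]
  if (length(hit)) hit[1] else NA_character_
}

# Second independent oracle: the model is exported in the BiGG JSON
# schema, re-parsed by cobrapy, and optimized with its GLPK backend —
# independent of both this package's reader and its simplex.
cobra_fba_objective <- function(model, objective) {
  doc <- list(
    id = "export",
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           charge = m$charge, formula = m$formula)
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, name = r$name,
           metabolites = as.list(model$stoichiometry[[r$id]]),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr,
           objective_coefficient = as.numeric(r$id == objective))
    }),
    genes = lapply(model$genes, function(g) list(id = g, name = g)),
    compartments = list(c = "cytosol", e = "extracellular"))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  script <- "
import sys, json
from cobra.io import load_json_model
m = load_json_model(sys.argv[1])
m.solver = 'glpk'
s = m.optimize()
print(json.dumps({'status': s.status, 'obj': s.objective_value}))
"
  out <- system2("python", c("-c", shQuote(script), f), stdout = TRUE,
                 stderr = FALSE)
  res <- jsonlite::fromJSON(out[length(out)])
  if (!identical(res$status, "optimal")) stop("cobra oracle not optimal: ",
                                              res$status)
  res$obj
}
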
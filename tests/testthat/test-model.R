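test_that("model construction enforces the structural invariants", {
  m <- core_m()
  expect_s3_class(m, "fba_model")
  expect_silent(validate_model(m))

  # duplicated reaction id
  bad <- m
  bad$reactions$id[2] <- bad$reactions$id[1]
  expect_error(fba_model(bad$metabolites, bad$reactions, bad$stoichiometry),
               "duplicate")

  # stoichiometry over an undeclared metabolite
  bad <- m
  bad$stoichiometry[["TPI"]] <- c(ghost_c = -1, g3p_c = 1)
  expect_error(validate_model(bad), "ghost_c")

  # inverted bounds
  bad <- m
  i <- match("TPI", bad$reactions$id)
  bad$reactions$lower_bound[i] <- 5
  bad$reactions$upper_bound[i] <- -5
  expect_error(validate_model(bad), "lower_bound > upper_bound")

  # GPR over a gene missing from the gene universe
  bad <- m
  bad$genes <- setdiff(bad$genes, "tpiA")
  expect_error(validate_model(bad), "tpiA")
})

test_that("stoichiometric matrix is metabolites x reactions in input order", {
  m <- core_m()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  expect_identical(rownames(S), m$metabolites$id)
  expect_identical(colnames(S), m$reactions$id)
  # column <-> reaction bijection with the exact coefficients
  for (rid in c("GLYK", "TPI", "BIOMASS_core")) {
    st <- m$stoichiometry[[rid]]
    col <- S[, rid]
    expect_equal(col[names(st)], st, ignore_attr = TRUE)
    expect_equal(sum(col != 0), length(st))
  }
  # every exchange column has exactly one nonzero entry
  for (ex in exchange_reactions(m)) {
    expect_equal(sum(S[, ex] != 0), 1L)
  }
  # deterministic: two builds are identical
  expect_identical(S, stoichiometric_matrix(m))
})

test_that("mass balance check flags corrupted reactions and skips boundaries", {
  m <- core_m()
  rep0 <- check_mass_balance(m)
  expect_equal(unique(rep0$status), "skipped")
  expect_true("EX_glyc_e" %in% rep0$reaction_id)
  expect_true("BIOMASS_core" %in% rep0$reaction_id)

  # drop the water product from glycerol kinase's ATP hydrolysis partner:
  # corrupt FBP (fdp + h2o -> f6p + pi) by removing the water
  bad <- m
  st <- bad$stoichiometry[["FBP"]]
  bad$stoichiometry[["FBP"]] <- st[names(st) != "h2o_c"]
  repb <- check_mass_balance(bad)
  imb <- repb[repb$reaction_id == "FBP" & repb$status == "imbalanced", ]
  expect_equal(imb$imbalance[imb$element == "H"], 2)
  expect_equal(imb$imbalance[imb$element == "O"], 1)

  # metabolite with no formula is reported, not fatal
  bad <- m
  bad$metabolites$formula[match("fdp_c", bad$metabolites$id)] <- ""
  repf <- check_mass_balance(bad)
  expect_true("missing_formula" %in%
                repf$status[repf$reaction_id == "FBP"])
})

test_that("net biomass carbon counts consumed minus produced carbon", {
  m <- core_m()
  # toy: biomass consuming 40 units of a C1 precursor
  met <- data.frame(id = c("x_c", "atp_c", "adp_c", "pi_c", "h2o_c", "h_c"),
                    name = "", formula = c("CH2O", "C10H12N5O13P3",
                                           "C10H12N5O10P2", "HO4P", "H2O", "H"),
                    charge = c(0L, -4L, -3L, -2L, 0L, 1L),
                    compartment = "c", stringsAsFactors = FALSE)
  rxn <- data.frame(id = "BIO", name = "", lower_bound = 0,
                    upper_bound = 1000, gpr = "", subsystem = "",
                    stringsAsFactors = FALSE)
  toy <- fba_model(met, rxn, list(BIO = c(x_c = -40)),
                   biomass_reaction_id = "BIO")
  expect_equal(net_biomass_carbon(toy), 40)
  # adding growth-associated ATP hydrolysis leaves net carbon unchanged
  toy2 <- toy
  toy2$stoichiometry[["BIO"]] <-
    c(x_c = -40, atp_c = -20, h2o_c = -20, adp_c = 20, pi_c = 20, h_c = 20)
  expect_equal(net_biomass_carbon(toy2), 40)
  # missing formula on a participant names the metabolite
  toy3 <- toy
  toy3$metabolites$formula[1] <- ""
  expect_error(net_biomass_carbon(toy3), "x_c")
  # fixture value: 10 pyr (C3) + 5 accoa (net C2 over CoA) per gDC
  expect_equal(net_biomass_carbon(m), 40)
})

test_that("native JSON dump round-trips a model exactly", {
  m <- prod_m()
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f, "native-json")
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  expect_identical(m2$metabolites$formula, m$metabolites$formula)
  for (rid in m$reactions$id) {
    expect_equal(sort(names(m2$stoichiometry[[rid]])),
                 sort(names(m$stoichiometry[[rid]])))
    expect_equal(m2$stoichiometry[[rid]][names(m$stoichiometry[[rid]])],
                 m$stoichiometry[[rid]])
  }
  expect_identical(m2$biomass_reaction_id, m$biomass_reaction_id)
  # identical models dump to byte-identical files
  f2 <- tempfile(fileext = ".json")
  save_model(load_model(f, "native-json"), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("BiGG JSON models load with bounds, GPRs and objective intact", {
  p <- write_bigg_fixture()
  m <- load_model(p, "bigg-json")
  expect_equal(nrow(m$reactions), 6)
  expect_equal(nrow(m$metabolites), 4)
  expect_setequal(m$genes, c("g_ptsG", "g_galP", "g_a", "g_b"))
  expect_identical(m$biomass_reaction_id, "BIOMASS_toy")
  i <- match("EX_glc__D_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -10)
  expect_identical(m$reactions$gpr[match("CAT", m$reactions$id)],
                   "g_a and g_b")
  expect_equal(m$stoichiometry[["CAT"]], c(glc__D_c = -1, co2_c = 6))
  # and it solves: glucose in, biomass out
  s <- solve_fba(m)
  expect_equal(s$objective_value, 10, tolerance = 1e-9)
})

test_that("SBML L3+FBC models load; formulas from fbc attribute or notes", {
  p <- write_sbml_fixture()
  m <- load_model(p, "sbml-fbc")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 3)
  # fbc:chemicalFormula path and legacy notes FORMULA path
  expect_identical(m$metabolites$formula[match("ac_e", m$metabolites$id)],
                   "C2H3O2")
  expect_identical(m$metabolites$formula[match("ac_c", m$metabolites$id)],
                   "C2H3O2")
  expect_equal(m$metabolites$charge[match("ac_e", m$metabolites$id)], -1L)
  # bounds resolved through the parameter table
  i <- match("EX_ac_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -10)
  # nested gene association rendered as a rule
  gpr <- m$reactions$gpr[match("ACt", m$reactions$id)]
  expect_true(evaluate_gpr(gpr, character(0)))
  expect_true(evaluate_gpr(gpr, c("x1")))          # isozyme survives
  expect_false(evaluate_gpr(gpr, c("actP", "x1"))) # both routes dead
  expect_identical(m$biomass_reaction_id, "BIOMASS_toy")
  expect_equal(solve_fba(m)$objective_value, 10, tolerance = 1e-9)
})

test_that("loader failure modes: truncation, missing biomass, bad dialect", {
  p <- write_bigg_fixture()
  txt <- readLines(p)
  half <- tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), half)
  expect_error(load_model(half, "bigg-json"))

  # remove the objective: error must list biomass-like candidates
  j <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  j$reactions <- lapply(j$reactions, function(r) {
    r$objective_coefficient <- 0
    r
  })
  nb <- tempfile(fileext = ".json")
  jsonlite::write_json(j, nb, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(nb, "bigg-json"), "BIOMASS_toy")
  # but an explicit override works
  m <- load_model(nb, "bigg-json", biomass_reaction_id = "BIOMASS_toy")
  expect_identical(m$biomass_reaction_id, "BIOMASS_toy")

  expect_error(load_model(tempfile(), "bigg-json"), "not found")
})
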
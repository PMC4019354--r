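test_that("the generated host model is valid, balanced, and grows", {
  m <- core_m()
  expect_silent(validate_model(m))
  # every non-boundary reaction conserves C, H, O (and N, P, S)
  rep <- check_mass_balance(m)
  expect_equal(nrow(rep[rep$status == "imbalanced", ]), 0)
  # it grows on glycerol under the microaerobic reference condition
  mc <- set_condition(m, condition(15, 10))
  s <- solve_fba(mc)
  expect_equal(s$status, "optimal")
  expect_gt(s$objective_value, 0)
  # charge is conserved too (the fixture is built strictly)
  repq <- check_mass_balance(m, elements = character(0), charge = TRUE)
  expect_equal(nrow(repq[repq$status == "imbalanced", ]), 0)
})

test_that("every enzymatic reaction carries a usable GPR", {
  m <- core_m()
  enz <- !m$reactions$id %in% c(exchange_reactions(m), "BIOMASS_core",
                                "ATPM") &
    !m$reactions$subsystem %in% "Transport"
  gprs <- m$reactions$gpr[enz]
  expect_true(all(nzchar(gprs)))
  # exactly one AND complex and one OR isozyme pair for GPR semantics
  expect_equal(sum(grepl(" and ", gprs)), 1)
  expect_equal(sum(grepl(" or ", gprs)), 1)
  # the screenable design genes are all present
  expect_true(all(setdiff(screen_genes, "yqhD") %in% m$genes))
})

test_that("spec parameters are respected and invalid specs rejected", {
  expect_error(core_model_spec(po_ratio = 0), "po_ratio")
  expect_error(core_model_spec(biomass_carbon = -1), "biomass_carbon")
  expect_error(core_model_spec(gam = -1), "gam")
  # biomass carbon scales the precursor drain
  m80 <- build_core_model(core_model_spec(biomass_carbon = 80))
  expect_equal(net_biomass_carbon(m80), 80)
  # flags prune the optional branches
  m_min <- build_core_model(core_model_spec(include_ed_pathway = FALSE,
                                            include_methylglyoxal = FALSE,
                                            include_ppp = FALSE))
  expect_false(any(c("EDD", "EDA", "MGSA", "GND") %in% m_min$reactions$id))
  # glycolysis via the isomerase still supports growth
  s <- solve_fba(set_condition(m_min, condition(15, 10)))
  expect_gt(s$objective_value, 0)
})

test_that("model generation is deterministic: byte-identical dumps", {
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_model(build_core_model(), f1)
  save_model(build_core_model(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("forcing zero growth, unlimited O2: 3HP yield reaches 100 C-mol%", {
  # By construction glycerol -> 3HPA -> 3HP neither consumes nor loses
  # carbon; the only side requirement is reoxidizing one NADH per 3HP,
  # which unlimited O2 absorbs.  The hand LP optimum is therefore full
  # conversion: 15 mmol 3HP on 15 mmol glycerol = 100 C-mol%.
  m <- set_condition(add_3hp_pathway(build_core_model()),
                     condition(15, 1000))
  i <- match("BIOMASS_core", m$reactions$id)
  m$reactions$upper_bound[i] <- 0
  s <- solve_fba(m, objective = "EX_3hp_e")
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 15, tolerance = 1e-6)
  y <- cmol_yield(s$objective_value, 3, -get_flux(s, "EX_glyc_e"), 3)
  expect_equal(y, 100, tolerance = 1e-6)
})

test_that("tpiA+zwf deletion reroutes carbon through methylglyoxal, not ED", {
  m <- prod_m()
  # tpiA alone: the ED cycle (via fructose-6-phosphate aldolase) keeps
  # the cell growing with the isomerase dead
  k1 <- apply_knockout(m, "tpiA")
  s1 <- solve_fba(k1)
  expect_gt(s1$objective_value, 0)
  # with zwf also gone the ED entry is blocked: flux through
  # methylglyoxal synthase appears and the product branch opens
  k2 <- apply_knockout(m, c("tpiA", "zwf"))
  s2 <- solve_lexicographic(k2, secondary = "EX_3hp_e")
  expect_equal(s2$status, "optimal")
  expect_gt(get_flux(s2, "MGSA"), 0)
  expect_equal(get_flux(s2, "EDD"), 0, tolerance = 1e-9)
  expect_gt(s2$objective_value, 1)      # 3HP flux becomes substantial
  expect_lt(s2$primary_value, s1$objective_value)  # growth cost
})
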
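test_that("carbon-molar yield arithmetic", {
  expect_equal(cmol_yield(15, 3, 15, 3), 100)
  expect_equal(cmol_yield(0, 3, 15, 3), 0)
  expect_equal(cmol_yield(10.575, 3, 15, 3), 70.5)
  # acetate (C2) on glycerol (C3)
  expect_equal(cmol_yield(9, 2, 12, 3), 50)
  expect_error(cmol_yield(1, 3, 0, 3), "positive")
  expect_error(cmol_yield(-1, 3, 15, 3), "non-negative")
})

test_that("cmol_yield is linear in product flux, inverse in substrate flux", {
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(1, 0, 20)
    s <- stats::runif(1, 1, 20)
    k <- stats::runif(1, 0.5, 3)
    expect_equal(cmol_yield(k * p, 3, s, 3), k * cmol_yield(p, 3, s, 3))
    expect_equal(cmol_yield(p, 3, k * s, 3), cmol_yield(p, 3, s, 3) / k)
  }
})

test_that("relative growth is a simple percentage with guarded input", {
  expect_equal(relative_growth(0.5, 0.5), 100)
  expect_equal(relative_growth(0, 0.7), 0)
  expect_error(relative_growth(0.1, 0), "positive")
})

test_that("yield table closes the carbon balance at 100 C-mol%", {
  m <- prod_m()
  for (genes in list(character(0), c("tpiA", "zwf"))) {
    km <- if (length(genes)) apply_knockout(m, genes) else m
    sol <- solve_lexicographic(km, secondary = "EX_3hp_e")
    yt <- yield_table(sol, km)
    expect_equal(yt$carbon_closure, 100, tolerance = 0.1)
    expect_true(all(yt$product_yields >= 0, na.rm = TRUE))
    expect_equal(yt$consumed_glycerol_flux, -get_flux(sol, "EX_glyc_e"))
  }
  # the tpiA/zwf knockout secretes no succinate and no 1,3-PDO at optimum
  km <- apply_knockout(m, c("tpiA", "zwf"))
  sol <- solve_lexicographic(km, secondary = "EX_3hp_e")
  yt <- yield_table(sol, km)
  expect_equal(unname(yt$product_yields[["succinate"]]), 0)
  expect_equal(unname(yt$product_yields[["13pdo"]]), 0, tolerance = 1e-3)
  # biomass yield ties growth to net biomass carbon on the uptake basis
  expect_equal(yt$biomass_yield,
               100 * yt$growth_rate * net_biomass_carbon(km) /
                 (yt$consumed_glycerol_flux * 3))
  # a solution with no uptake has no yield basis
  closed <- m
  i <- match(exchange_reactions(m), closed$reactions$id)
  closed$reactions$lower_bound[i] <- 0
  s0 <- solve_fba(closed)
  expect_error(yield_table(s0, closed), "no substrate")
})

test_that("flux maps are normalized to glycerol uptake = 100%", {
  m <- prod_m()
  km <- apply_knockout(m, "tpiA")
  sol <- solve_lexicographic(km, secondary = "EX_3hp_e")
  fm <- normalize_flux_map(sol, c("EX_glyc_e", "TPI", "MGSA", "GLYK"))
  expect_equal(unname(fm[["EX_glyc_e"]]), -100)   # uptake is negative flux
  expect_equal(unname(fm[["TPI"]]), 0)            # deleted reaction
  expect_error(normalize_flux_map(sol, "NOT_A_REACTION"), "unknown")
  # the tpiA+zwf knockout leaves the Entner-Doudoroff branch silent
  km2 <- apply_knockout(m, c("tpiA", "zwf"))
  sol2 <- solve_lexicographic(km2, secondary = "EX_3hp_e")
  fm2 <- normalize_flux_map(sol2, c("EDD", "EDA", "MGSA"))
  expect_equal(unname(fm2[["EDD"]]), 0)
  expect_gt(unname(fm2[["MGSA"]]), 0)
})

test_that("OUR sweep matches single runs and grows monotonically with O2", {
  host <- add_3hp_pathway(build_core_model())
  km <- apply_knockout(host, c("tpiA", "zwf"))
  ours <- c(0, 2.5, 5, 7.5, 10, 12.5, 15)
  sw <- our_sweep(km, gur = 15, our_values = ours)
  expect_equal(sw$our, ours)
  # the OUR = 10 row equals the single-run result
  single <- solve_lexicographic(set_condition(km, condition(15, 10)),
                                secondary = "EX_3hp_e")
  i <- match(10, sw$our)
  expect_equal(sw$growth_rate[i], single$primary_value, tolerance = 1e-9)
  expect_equal(sw$threehp_flux[i], single$objective_value, tolerance = 1e-9)
  # growth is non-decreasing in oxygen availability
  expect_true(all(diff(sw$growth_rate) >= -1e-6))
  expect_error(our_sweep(km, our_values = c(-1, 5)), "non-negative")
})
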
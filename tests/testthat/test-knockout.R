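test_that("gene deletion disables exactly the GPR-dead reactions", {
  m <- prod_m()
  # one-gene rules
  expect_identical(disabled_reactions(m, "tpiA"), "TPI")
  expect_identical(disabled_reactions(m, "zwf"), "ZWF")
  km <- apply_knockout(m, "tpiA")
  i <- match("TPI", km$reactions$id)
  expect_equal(km$reactions$lower_bound[i], 0)
  expect_equal(km$reactions$upper_bound[i], 0)
  # input untouched
  expect_lt(m$reactions$lower_bound[i], 0)
  # AND complex: either subunit kills pyruvate dehydrogenase
  expect_identical(disabled_reactions(m, "aceE"), "PDH")
  expect_identical(disabled_reactions(m, "aceF"), "PDH")
  # OR isozyme pair: single deletion disables nothing
  expect_length(disabled_reactions(m, "ackA"), 0)
  expect_identical(disabled_reactions(m, c("ackA", "tdcD")), "ACK")
  # yqhD (host gene on the grafted branch) disables the PDO oxidoreductase
  expect_identical(disabled_reactions(m, "yqhD"), "PDOR")
})

test_that("unknown gene ids error with near-matches", {
  m <- prod_m()
  expect_error(apply_knockout(m, "tpia"), "did you mean.*tpiA")
  expect_error(apply_knockout(m, "nosuchgene"), "unknown gene")
})

test_that("single knockout screen equals per-gene manual solves", {
  m <- prod_m()
  genes <- screen_genes
  scr <- single_knockout_screen(m, genes = genes)
  expect_equal(nrow(scr), length(genes))
  mu_wt <- solve_fba(m)$objective_value
  for (k in seq_along(genes)) {
    sol <- solve_lexicographic(apply_knockout(m, genes[k]),
                               secondary = "EX_3hp_e")
    row <- scr[scr$gene_1 == genes[k], ]
    expect_equal(row$growth_rate, sol$primary_value, tolerance = 1e-9)
    expect_equal(row$threehp_flux, max(sol$objective_value, 0),
                 tolerance = 1e-9)
    expect_equal(row$relative_growth_pct,
                 100 * sol$primary_value / mu_wt, tolerance = 1e-9)
  }
  # no knockout grows faster than wild-type; yields stay in [0, 100]
  expect_true(all(scr$relative_growth_pct <= 100 + 1e-6))
  expect_true(all(scr$threehp_yield_cmol_pct >= 0 &
                    scr$threehp_yield_cmol_pct <= 100 + 1e-6))
  # empty gene list gives an empty table
  expect_equal(nrow(single_knockout_screen(m, genes = character(0))), 0)
})

test_that("double knockout screen equals brute force over all pairs", {
  m <- prod_m()
  genes <- c("tpiA", "zwf", "gldA", "mgsA", "yqhD")     # 10 pairs
  scr <- double_knockout_screen(m, genes = genes)
  full <- attr(scr, "full_table")
  expect_equal(nrow(full), choose(5, 2))
  mu_wt <- solve_fba(m)$objective_value
  for (r in seq_len(nrow(full))) {
    pair <- c(full$gene_1[r], full$gene_2[r])
    sol <- solve_lexicographic(apply_knockout(m, pair),
                               secondary = "EX_3hp_e")
    mu <- if (sol$status == "optimal") sol$primary_value else 0
    expect_equal(full$growth_rate[r], mu, tolerance = 1e-9)
    if (mu > 1e-9) {
      expect_equal(full$threehp_flux[r], max(sol$objective_value, 0),
                   tolerance = 1e-9)
    }
  }
  # ranking is by yield, then relative growth, then gene ids
  y <- full$threehp_yield_cmol_pct
  expect_true(all(diff(y) <= 1e-12 + 1e-9 * abs(y[-length(y)])))
  # a single gene yields an empty pair table
  expect_equal(nrow(double_knockout_screen(m, genes = "tpiA")), 0)
})

test_that("double deletions obey set and growth monotonicity", {
  m <- prod_m()
  mu1 <- vapply(screen_genes, function(g) {
    s <- solve_fba(apply_knockout(m, g))
    if (s$status == "optimal") s$objective_value else 0
  }, numeric(1))
  pairs <- utils::combn(screen_genes, 2, simplify = FALSE)
  for (p in pairs) {
    dr_pair <- disabled_reactions(m, p)
    dr_union <- union(disabled_reactions(m, p[1]),
                      disabled_reactions(m, p[2]))
    expect_true(all(dr_union %in% dr_pair))
    s <- solve_fba(apply_knockout(m, p))
    mu_pair <- if (s$status == "optimal") s$objective_value else 0
    expect_lte(mu_pair, min(mu1[p]) + 1e-6)
  }
})

test_that("deletions with identical disabled sets share one record", {
  m <- prod_m()
  # aceE and aceF each kill only PDH, so the records must be identical
  scr <- double_knockout_screen(m, genes = c("aceE", "aceF", "tpiA"))
  full <- attr(scr, "full_table")
  a <- full[full$gene_1 == "aceE" & full$gene_2 == "tpiA", ]
  b <- full[full$gene_1 == "aceF" & full$gene_2 == "tpiA", ]
  expect_equal(a$growth_rate, b$growth_rate)
  expect_equal(a$threehp_yield_cmol_pct, b$threehp_yield_cmol_pct)
  expect_equal(a$n_reactions_disabled, b$n_reactions_disabled)
})

test_that("pathway pseudo-genes are excluded from default screens", {
  m <- prod_m()
  scr <- single_knockout_screen(m)
  expect_false(any(scr$gene_1 %in% pathway_pseudogenes()))
  expect_true("yqhD" %in% scr$gene_1)   # host gene stays screenable
})
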
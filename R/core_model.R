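#' Specification for the reduced central-carbon E. coli model
#'
#' Parameters of the synthetic host model built by [build_core_model()].
#' The generated network stands in for a genome-scale E. coli model in
#' tests and examples: it carries both glycerol assimilation routes
#' (ATP-dependent glycerol kinase / aerobic G3P dehydrogenase, and
#' glycerol dehydrogenase / PEP-dependent dihydroxyacetone kinase),
#' lower glycolysis, the gluconeogenic FBP arm, the oxidative pentose
#' phosphate branch, the Entner-Doudoroff pathway, the methylglyoxal
#' shunt, fructose-6-phosphate aldolase, pyruvate dehydrogenase and
#' formate lyase, a lumped TCA cycle, fermentative acetate / ethanol /
#' lactate / succinate branches, lumped respiration, transhydrogenase,
#' ATP maintenance and a single lumped biomass drain.
#'
#' @param include_ed_pathway include the Entner-Doudoroff reactions
#'   (edd/eda).
#' @param include_methylglyoxal include the methylglyoxal shunt
#'   (mgsA and the glyoxalase route to D-lactate).
#' @param include_ppp include the oxidative pentose phosphate branch
#'   (gnd) and the lumped non-oxidative return.
#' @param po_ratio mol ATP recovered per mol NADH through the lumped
#'   respiratory chain; 1.5 is a conventional mid-range value for
#'   E. coli growing on glycerol.
#' @param gam growth-associated ATP demand, mmol ATP per gDC.
#' @param biomass_carbon net carbon drained into biomass, mmol C per
#'   gDC; 40 is the round figure for ~0.48 gC/gDC dry biomass.
#' @return a `core_model_spec` list.
#' @export
core_model_spec <- function(include_ed_pathway = TRUE,
                            include_methylglyoxal = TRUE,
                            include_ppp = TRUE,
                            po_ratio = 1.5,
                            gam = 8.39,
                            biomass_carbon = 40) {
  if (po_ratio <= 0) stop("po_ratio must be positive")
  if (biomass_carbon <= 0) stop("biomass_carbon must be positive")
  if (gam < 0) stop("gam must be non-negative")
  structure(list(include_ed_pathway = include_ed_pathway,
                 include_methylglyoxal = include_methylglyoxal,
                 include_ppp = include_ppp,
                 po_ratio = po_ratio,
                 gam = gam,
                 biomass_carbon = biomass_carbon),
            class = "core_model_spec")
}

#' Build the reduced central-carbon host model
#'
#' Constructs the ~40-reaction glycerol-fed E. coli model described in
#' [core_model_spec()].  Every metabolite carries its real chemical
#' formula and charge, every non-boundary reaction is elementally
#' balanced (C, H, O, N, P, S and charge), and every enzymatic reaction
#' carries a one-gene GPR (plus one AND complex, pyruvate dehydrogenase,
#' and one OR isozyme pair, acetate kinase, to exercise GPR semantics).
#' Construction is deterministic: the same spec always yields a model
#' whose native JSON dump is byte-identical.
#'
#' The model is built with all carbon exchanges closed to uptake; apply
#' [set_condition()] to feed it glycerol.
#'
#' @param spec a [core_model_spec()].
#' @return an [fba_model] with biomass reaction `"BIOMASS_core"`.
#' @export
build_core_model <- function(spec = core_model_spec()) {
  stopifnot(inherits(spec, "core_model_spec"))
  po <- spec$po_ratio
  fC <- spec$biomass_carbon / 40     # scale of the precursor drain

  mets <- list(
    ## id, name, formula, charge; compartment suffix decides compartment
    c("glyc_e",    "Glycerol",                    "C3H8O3",           "0"),
    c("glyc_c",    "Glycerol",                    "C3H8O3",           "0"),
    c("glyc3p_c",  "Glycerol 3-phosphate",        "C3H7O6P",          "-2"),
    c("dha_c",     "Dihydroxyacetone",            "C3H6O3",           "0"),
    c("dhap_c",    "Dihydroxyacetone phosphate",  "C3H5O6P",          "-2"),
    c("g3p_c",     "Glyceraldehyde 3-phosphate",  "C3H5O6P",          "-2"),
    c("fdp_c",     "Fructose 1,6-bisphosphate",   "C6H10O12P2",       "-4"),
    c("f6p_c",     "Fructose 6-phosphate",        "C6H11O9P",         "-2"),
    c("g6p_c",     "Glucose 6-phosphate",         "C6H11O9P",         "-2"),
    c("6pgc_c",    "6-phospho-gluconate",         "C6H10O10P",        "-3"),
    c("2ddg6p_c",  "2-dehydro-3-deoxy-gluconate 6-phosphate", "C6H8O9P", "-3"),
    c("ru5p__D_c", "Ribulose 5-phosphate",        "C5H9O8P",          "-2"),
    c("mthgxl_c",  "Methylglyoxal",               "C3H4O2",           "0"),
    c("lac__D_c",  "D-lactate",                   "C3H5O3",           "-1"),
    c("lac__D_e",  "D-lactate",                   "C3H5O3",           "-1"),
    c("pep_c",     "Phosphoenolpyruvate",         "C3H2O6P",          "-3"),
    c("pyr_c",     "Pyruvate",                    "C3H3O3",           "-1"),
    c("accoa_c",   "Acetyl-CoA",                  "C23H34N7O17P3S",   "-4"),
    c("coa_c",     "Coenzyme A",                  "C21H32N7O16P3S",   "-4"),
    c("ac_c",      "Acetate",                     "C2H3O2",           "-1"),
    c("ac_e",      "Acetate",                     "C2H3O2",           "-1"),
    c("etoh_c",    "Ethanol",                     "C2H6O",            "0"),
    c("etoh_e",    "Ethanol",                     "C2H6O",            "0"),
    c("for_c",     "Formate",                     "CHO2",             "-1"),
    c("for_e",     "Formate",                     "CHO2",             "-1"),
    c("succ_c",    "Succinate",                   "C4H4O4",           "-2"),
    c("succ_e",    "Succinate",                   "C4H4O4",           "-2"),
    c("co2_c",     "Carbon dioxide",              "CO2",              "0"),
    c("co2_e",     "Carbon dioxide",              "CO2",              "0"),
    c("o2_c",      "Oxygen",                      "O2",               "0"),
    c("o2_e",      "Oxygen",                      "O2",               "0"),
    c("h2o_c",     "Water",                       "H2O",              "0"),
    c("h2o_e",     "Water",                       "H2O",              "0"),
    c("h_c",       "Proton",                      "H",                "1"),
    c("h_e",       "Proton",                      "H",                "1"),
    c("pi_c",      "Phosphate",                   "HO4P",             "-2"),
    c("pi_e",      "Phosphate",                   "HO4P",             "-2"),
    c("nh4_c",     "Ammonium",                    "H4N",              "1"),
    c("nh4_e",     "Ammonium",                    "H4N",              "1"),
    c("atp_c",     "ATP",                         "C10H12N5O13P3",    "-4"),
    c("adp_c",     "ADP",                         "C10H12N5O10P2",    "-3"),
    c("nad_c",     "NAD+",                        "C21H26N7O14P2",    "-1"),
    c("nadh_c",    "NADH",                        "C21H27N7O14P2",    "-2"),
    c("nadp_c",    "NADP+",                       "C21H25N7O17P3",    "-3"),
    c("nadph_c",   "NADPH",                       "C21H26N7O17P3",    "-4"))
  metabolites <- data.frame(
    id = vapply(mets, `[`, "", 1L),
    name = vapply(mets, `[`, "", 2L),
    formula = vapply(mets, `[`, "", 3L),
    charge = as.integer(vapply(mets, `[`, "", 4L)),
    compartment = sub("^.*_([ce])$", "\\1", vapply(mets, `[`, "", 1L)),
    stringsAsFactors = FALSE)

  rx <- list()
  add <- function(id, name, st, lb, ub, gpr = "", sub = "") {
    rx[[length(rx) + 1L]] <<- list(id = id, name = name, st = st,
                                   lb = lb, ub = ub, gpr = gpr, sub = sub)
  }
  M <- 1000

  ## --- boundary exchanges (BiGG convention: positive = secretion) ----
  add("EX_glyc_e", "Glycerol exchange", c(glyc_e = -1), 0, M, sub = "Exchange")
  add("EX_o2_e",  "O2 exchange",  c(o2_e  = -1), -M, M, sub = "Exchange")
  add("EX_co2_e", "CO2 exchange", c(co2_e = -1), -M, M, sub = "Exchange")
  add("EX_h2o_e", "H2O exchange", c(h2o_e = -1), -M, M, sub = "Exchange")
  add("EX_h_e",   "H+ exchange",  c(h_e   = -1), -M, M, sub = "Exchange")
  add("EX_pi_e",  "Phosphate exchange", c(pi_e = -1), -M, M, sub = "Exchange")
  add("EX_nh4_e", "Ammonium exchange",  c(nh4_e = -1), -M, M, sub = "Exchange")
  add("EX_ac_e",  "Acetate exchange",   c(ac_e = -1), 0, M, sub = "Exchange")
  add("EX_etoh_e", "Ethanol exchange",  c(etoh_e = -1), 0, M, sub = "Exchange")
  add("EX_for_e", "Formate exchange",   c(for_e = -1), 0, M, sub = "Exchange")
  add("EX_lac__D_e", "D-lactate exchange", c(lac__D_e = -1), 0, M,
      sub = "Exchange")
  add("EX_succ_e", "Succinate exchange", c(succ_e = -1), 0, M,
      sub = "Exchange")

  ## --- transport ------------------------------------------------------
  add("GLYCt", "Glycerol facilitated diffusion",
      c(glyc_e = -1, glyc_c = 1), -M, M, "glpF", "Transport")
  add("O2t",  "O2 diffusion",  c(o2_e = -1, o2_c = 1), -M, M, "", "Transport")
  add("CO2t", "CO2 diffusion", c(co2_e = -1, co2_c = 1), -M, M, "", "Transport")
  add("H2Ot", "H2O diffusion", c(h2o_e = -1, h2o_c = 1), -M, M, "", "Transport")
  add("Ht",   "Proton diffusion", c(h_e = -1, h_c = 1), -M, M, "", "Transport")
  add("PIt",  "Phosphate/H+ symport",
      c(pi_e = -1, h_e = -1, pi_c = 1, h_c = 1), -M, M, "pitA", "Transport")
  add("NH4t", "Ammonium transport", c(nh4_e = -1, nh4_c = 1), -M, M, "",
      "Transport")
  add("ACt",  "Acetate/H+ symport",
      c(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1), -M, M, "", "Transport")
  add("ETOHt", "Ethanol diffusion", c(etoh_c = -1, etoh_e = 1), -M, M, "",
      "Transport")
  add("FORt", "Formate transport", c(for_c = -1, for_e = 1), -M, M, "",
      "Transport")
  add("D_LACt", "D-lactate/H+ symport",
      c(lac__D_c = -1, h_c = -1, lac__D_e = 1, h_e = 1), -M, M, "",
      "Transport")
  add("SUCCt", "Succinate transport", c(succ_c = -1, succ_e = 1), -M, M, "",
      "Transport")

  ## --- glycerol assimilation -----------------------------------------
  add("GLYK", "Glycerol kinase",
      c(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1, h_c = 1),
      0, M, "glpK", "Glycerol metabolism")
  add("G3PD", "Glycerol-3-phosphate dehydrogenase (aerobic, lumped to O2)",
      c(glyc3p_c = -1, o2_c = -0.5, dhap_c = 1, h2o_c = 1),
      0, M, "glpD", "Glycerol metabolism")
  add("GLYCDH", "Glycerol dehydrogenase",
      c(glyc_c = -1, nad_c = -1, dha_c = 1, nadh_c = 1, h_c = 1),
      0, M, "gldA", "Glycerol metabolism")
  add("DHAPT", "Dihydroxyacetone kinase (PEP-dependent)",
      c(dha_c = -1, pep_c = -1, dhap_c = 1, pyr_c = 1),
      0, M, "dhaK", "Glycerol metabolism")

  ## --- glycolysis / gluconeogenesis ----------------------------------
  add("TPI", "Triosephosphate isomerase", c(dhap_c = -1, g3p_c = 1),
      -M, M, "tpiA", "Glycolysis")
  add("GLYCL", "Lower glycolysis (GAP to PEP, lumped)",
      c(g3p_c = -1, pi_c = -1, nad_c = -1, adp_c = -1,
        pep_c = 1, nadh_c = 1, atp_c = 1, h2o_c = 1, h_c = 1),
      0, M, "gapA", "Glycolysis")
  add("PYK", "Pyruvate kinase",
      c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
      0, M, "pykF", "Glycolysis")
  add("FBA", "Fructose-bisphosphate aldolase",
      c(dhap_c = -1, g3p_c = -1, fdp_c = 1), -M, M, "fbaA", "Glycolysis")
  add("FBP", "Fructose-1,6-bisphosphatase",
      c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1),
      0, M, "fbp", "Gluconeogenesis")
  add("PGI", "Glucose-6-phosphate isomerase", c(f6p_c = -1, g6p_c = 1),
      -M, M, "pgi", "Glycolysis")
  add("FSA", "Fructose-6-phosphate aldolase",
      c(f6p_c = -1, dha_c = 1, g3p_c = 1), -M, M, "fsaB", "Glycolysis")

  ## --- oxidative PPP entry and Entner-Doudoroff ----------------------
  add("ZWF", "Glucose-6-phosphate dehydrogenase (with lactonase, lumped)",
      c(g6p_c = -1, nadp_c = -1, h2o_c = -1,
        `6pgc_c` = 1, nadph_c = 1, h_c = 2),
      0, M, "zwf", "Pentose phosphate pathway")
  if (spec$include_ppp) {
    add("GND", "6-phosphogluconate dehydrogenase",
        c(`6pgc_c` = -1, nadp_c = -1, ru5p__D_c = 1, co2_c = 1, nadph_c = 1),
        0, M, "gnd", "Pentose phosphate pathway")
    add("PPPNONOX", "Non-oxidative pentose phosphate (lumped)",
        c(ru5p__D_c = -3, f6p_c = 2, g3p_c = 1),
        -M, M, "tktA", "Pentose phosphate pathway")
  }
  if (spec$include_ed_pathway) {
    add("EDD", "6-phosphogluconate dehydratase",
        c(`6pgc_c` = -1, `2ddg6p_c` = 1, h2o_c = 1),
        0, M, "edd", "Entner-Doudoroff")
    add("EDA", "KDPG aldolase",
        c(`2ddg6p_c` = -1, pyr_c = 1, g3p_c = 1),
        0, M, "eda", "Entner-Doudoroff")
  }

  ## --- methylglyoxal shunt -------------------------------------------
  if (spec$include_methylglyoxal) {
    add("MGSA", "Methylglyoxal synthase",
        c(dhap_c = -1, mthgxl_c = 1, pi_c = 1),
        0, M, "mgsA", "Methylglyoxal shunt")
    add("MGXDET", "Glyoxalase route, methylglyoxal to D-lactate (lumped)",
        c(mthgxl_c = -1, h2o_c = -1, lac__D_c = 1, h_c = 1),
        0, M, "gloA", "Methylglyoxal shunt")
  }
  add("LDH_D", "D-lactate dehydrogenase (NAD)",
      c(pyr_c = -1, nadh_c = -1, h_c = -1, lac__D_c = 1, nad_c = 1),
      -M, M, "ldhA", "Fermentation")

  ## --- pyruvate node, TCA, fermentation ------------------------------
  add("PDH", "Pyruvate dehydrogenase",
      c(pyr_c = -1, coa_c = -1, nad_c = -1,
        accoa_c = 1, co2_c = 1, nadh_c = 1),
      0, M, "aceE and aceF", "Pyruvate metabolism")
  add("PFL", "Pyruvate formate-lyase",
      c(pyr_c = -1, coa_c = -1, accoa_c = 1, for_c = 1),
      0, M, "pflB", "Pyruvate metabolism")
  add("ACK", "Acetate kinase (with phosphotransacetylase, lumped)",
      c(accoa_c = -1, adp_c = -1, pi_c = -1, ac_c = 1, atp_c = 1, coa_c = 1),
      0, M, "ackA or tdcD", "Fermentation")
  add("ALCD", "Acetaldehyde/alcohol dehydrogenase (lumped)",
      c(accoa_c = -1, nadh_c = -2, h_c = -2, etoh_c = 1, coa_c = 1, nad_c = 2),
      0, M, "adhE", "Fermentation")
  add("TCA", "TCA cycle (lumped; FADH2 counted as NADH)",
      c(accoa_c = -1, h2o_c = -2, nad_c = -4, adp_c = -1, pi_c = -1,
        co2_c = 2, coa_c = 1, nadh_c = 4, atp_c = 1, h_c = 3),
      0, M, "gltA", "TCA cycle")
  add("PPCFRD", "PEP carboxylation to succinate (lumped reductive branch)",
      c(pep_c = -1, co2_c = -1, nadh_c = -2, h_c = -1,
        succ_c = 1, pi_c = 1, nad_c = 2),
      0, M, "ppc", "Anaplerosis")

  ## --- energy and redox ----------------------------------------------
  add("RESP", "Respiratory chain (lumped NADH oxidase + ATP synthase)",
      c(nadh_c = -1, o2_c = -0.5, h_c = -(1 + po), adp_c = -po, pi_c = -po,
        nad_c = 1, h2o_c = 1 + po, atp_c = po),
      0, M, "nuoA", "Oxidative phosphorylation")
  add("THD", "Transhydrogenase",
      c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
      -M, M, "pntA", "Redox")
  add("ATPM", "ATP maintenance",
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      0, M, "", "Maintenance")

  ## --- biomass --------------------------------------------------------
  add("BIOMASS_core", "Biomass (lumped precursor drain)",
      c(pyr_c = -10 * fC, accoa_c = -5 * fC, nadph_c = -18 * fC,
        nh4_c = -10 * fC, atp_c = -spec$gam, h2o_c = -spec$gam,
        coa_c = 5 * fC, nadp_c = 18 * fC, adp_c = spec$gam,
        pi_c = spec$gam, h_c = spec$gam),
      0, M, "", "Biomass")

  reactions <- data.frame(
    id = vapply(rx, function(r) r$id, ""),
    name = vapply(rx, function(r) r$name, ""),
    lower_bound = vapply(rx, function(r) r$lb, 0),
    upper_bound = vapply(rx, function(r) r$ub, 0),
    gpr = vapply(rx, function(r) r$gpr, ""),
    subsystem = vapply(rx, function(r) r$sub, ""),
    stringsAsFactors = FALSE)
  stoich <- lapply(rx, function(r) r$st)
  names(stoich) <- reactions$id
  fba_model(metabolites, reactions, stoich,
            biomass_reaction_id = "BIOMASS_core")
}
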
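# Tiny model files in the two external dialects, generated at test time.

write_bigg_fixture <- function(path = tempfile(fileext = ".json")) {
  doc <- list(
    id = "toy",
    metabolites = list(
      list(id = "glc__D_e", name = "D-glucose", formula = "C6H12O6",
           charge = 0L, compartment = "e"),
      list(id = "glc__D_c", name = "D-glucose", formula = "C6H12O6",
           charge = 0L, compartment = "c"),
      list(id = "co2_e", name = "CO2", formula = "CO2", charge = 0L,
           compartment = "e"),
      list(id = "co2_c", name = "CO2", formula = "CO2", charge = 0L,
           compartment = "c")),
    reactions = list(
      list(id = "EX_glc__D_e", name = "Glucose exchange",
           metabolites = list(glc__D_e = -1), lower_bound = -10,
           upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 0),
      list(id = "GLCt", name = "Glucose transport",
           metabolites = list(glc__D_e = -1, glc__D_c = 1),
           lower_bound = -1000, upper_bound = 1000,
           gene_reaction_rule = "g_ptsG or g_galP",
           objective_coefficient = 0),
      list(id = "CAT", name = "Catabolism (lumped)",
           metabolites = list(glc__D_c = -1, co2_c = 6),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "g_a and g_b", objective_coefficient = 0),
      list(id = "CO2t", name = "CO2 transport",
           metabolites = list(co2_c = -1, co2_e = 1),
           lower_bound = -1000, upper_bound = 1000,
           gene_reaction_rule = "", objective_coefficient = 0),
      list(id = "EX_co2_e", name = "CO2 exchange",
           metabolites = list(co2_e = -1), lower_bound = -1000,
           upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 0),
      list(id = "BIOMASS_toy", name = "Biomass",
           metabolites = list(glc__D_c = -1), lower_bound = 0,
           upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 1)),
    genes = list(list(id = "g_ptsG"), list(id = "g_galP"),
                 list(id = "g_a"), list(id = "g_b")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# SBML L3 + FBC v2; one species carries fbc:chemicalFormula, one only a
# legacy notes FORMULA line, to exercise both lookup paths.
write_sbml_fixture <- function(path = tempfile(fileext = ".xml")) {
  xml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="lb_m1000" value="-1000" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="M_ac_e" name="Acetate" compartment="e"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false" fbc:charge="-1" fbc:chemicalFormula="C2H3O2"/>
      <species id="M_ac_c" name="Acetate" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false" fbc:charge="-1">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>FORMULA: C2H3O2</p>
          </body>
        </notes>
      </species>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_ac_e" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="M_ac_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_ACt" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m1000" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="M_ac_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_ac_c" stoichiometry="1"
                            constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_actP"/>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_x1"/>
              <fbc:geneProductRef fbc:geneProduct="G_x2"/>
            </fbc:and>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_BIOMASS_toy" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="M_ac_c" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIOMASS_toy"
                             fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_actP" fbc:label="actP"/>
      <fbc:geneProduct fbc:id="G_x1" fbc:label="x1"/>
      <fbc:geneProduct fbc:id="G_x2" fbc:label="x2"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>'
  writeLines(xml, path)
  path
}
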
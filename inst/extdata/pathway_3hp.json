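{
  "pathway": "3hp_13pdo_from_glycerol",
  "description": "Heterologous 3-hydroxypropionic acid / 1,3-propanediol pathway: glycerol dehydratase (dhaB, gdrAB) and aldehyde dehydrogenase (aldH) with the native yqhD oxidoreductase side branch. 3HP is the -1 anion; its export is a proton symport, 1,3-PDO export is diffusion.",
  "metabolites": [
    {"id": "3hpa_c",  "name": "3-hydroxypropionaldehyde", "formula": "C3H6O2", "charge": 0,  "compartment": "c"},
    {"id": "3hp_c",   "name": "3-hydroxypropionate",      "formula": "C3H5O3", "charge": -1, "compartment": "c"},
    {"id": "3hp_e",   "name": "3-hydroxypropionate",      "formula": "C3H5O3", "charge": -1, "compartment": "e"},
    {"id": "13pdo_c", "name": "1,3-propanediol",          "formula": "C3H8O2", "charge": 0,  "compartment": "c"},
    {"id": "13pdo_e", "name": "1,3-propanediol",          "formula": "C3H8O2", "charge": 0,  "compartment": "e"}
  ],
  "reactions": [
    {"id": "GLYCDHYD", "name": "Glycerol dehydratase",
     "stoichiometry": {"glyc_c": -1, "3hpa_c": 1, "h2o_c": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "dhaB and gdrAB", "subsystem": "3HP pathway"},
    {"id": "ALDD3HP", "name": "3HPA dehydrogenase",
     "stoichiometry": {"3hpa_c": -1, "nad_c": -1, "h2o_c": -1,
                       "3hp_c": 1, "nadh_c": 1, "h_c": 2},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "aldH", "subsystem": "3HP pathway"},
    {"id": "3HPt", "name": "3HP transporter (proton symport, outward)",
     "stoichiometry": {"3hp_c": -1, "h_c": -1, "3hp_e": 1, "h_e": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "", "subsystem": "3HP pathway"},
    {"id": "EX_3hp_e", "name": "3HP exchange",
     "stoichiometry": {"3hp_e": -1},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "", "subsystem": "Exchange"},
    {"id": "PDOR", "name": "1,3-propanediol oxidoreductase",
     "stoichiometry": {"3hpa_c": -1, "nadph_c": -1, "h_c": -1,
                       "13pdo_c": 1, "nadp_c": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "yqhD", "subsystem": "3HP pathway"},
    {"id": "PDOt", "name": "1,3-propanediol diffusion",
     "stoichiometry": {"13pdo_c": -1, "13pdo_e": 1},
     "lower_bound": -1000, "upper_bound": 1000,
     "gpr": "", "subsystem": "3HP pathway"},
    {"id": "EX_13pdo_e", "name": "1,3-PDO exchange",
     "stoichiometry": {"13pdo_e": -1},
     "lower_bound": 0, "upper_bound": 1000,
     "gpr": "", "subsystem": "Exchange"}
  ]
}
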
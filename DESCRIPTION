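Package: fbascreen
Title: Flux Balance Analysis and Gene-Knockout Screening for Metabolic
    Strain Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based modeling toolkit for designing microbial
    production strains.  Reads genome-scale metabolic models (BiGG JSON,
    SBML Level 3 FBC, or a native JSON dump), grafts a heterologous
    3-hydroxypropionic acid / 1,3-propanediol pathway onto an Escherichia
    coli host, and solves flux balance analysis problems with a built-in
    bounded-variable simplex, including the two-stage lexicographic
    variant that maximizes product flux at fixed maximal growth.
    Gene deletions are propagated through boolean gene-protein-reaction
    rules; exhaustive single- and double-knockout screens are ranked by
    carbon-molar product yield.  Includes a fully specified reduced
    central-carbon E. coli model (glycerol routes, glycolysis,
    Entner-Doudoroff, methylglyoxal shunt, TCA, fermentation branches)
    so the whole pipeline is testable without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Matrix,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
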
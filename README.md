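# fbascreen

Constraint-based strain design for 3-hydroxypropionic acid (3HP)
production from glycerol in *Escherichia coli*.

3HP is a platform chemical (precursor of acrylic acid and
poly(3HP) bioplastics), and glycerol — the glut byproduct of biodiesel
refining — is a cheap substrate for making it. *E. coli* has no native
3HP pathway; expressing a glycerol dehydratase (*dhaB*/*gdrAB*) and an
aldehyde dehydrogenase (*aldH*) creates one, but the producer strain
still routes most carbon into growth and acetate. `fbascreen` asks the
strain-design question computationally: **which central-metabolism gene
deletions force carbon into 3HP?**

The package provides, end to end:

* a data model for genome-scale metabolic networks (metabolite
  formulas/charges, reaction bounds, boolean gene–protein–reaction
  rules), with readers for BiGG JSON and SBML Level 3 FBC and a native
  JSON dump, plus elemental mass-balance auditing;
* grafting of the seven heterologous 3HP / 1,3-propanediol reactions
  onto a host model, and culture conditioning (glycerol uptake rate
  GUR, oxygen uptake rate OUR, all other carbon sources closed);
* flux balance analysis on a built-in bounded-variable simplex, solving

  ```
  maximize    cᵀ v
  subject to  S v = 0,   v_min ≤ v ≤ v_max
  ```

  including the two-stage lexicographic variant: maximize growth μ
  first, then maximize product export with μ pinned at its optimum, so
  the reported product flux is never an artifact of degenerate optima;
* GPR-mediated single and double gene-knockout screens ranked by
  carbon-molar product yield,
  `C-mol% = 100 · (v_product · C_product) / (v_substrate · C_substrate)`;
* yield tables, flux maps normalized to glycerol uptake, and an OUR
  sweep for aerobiosis profiling;
* a fully specified ~50-reaction reduced central-carbon *E. coli* model
  (both glycerol routes, glycolysis, Entner–Doudoroff, pentose
  phosphate, methylglyoxal shunt, TCA, fermentation branches, lumped
  respiration and biomass) so the entire pipeline runs and is tested
  without downloading any external model.

## Worked example

Build the producer model, delete *tpiA* (triosephosphate isomerase) and
*zwf* (glucose-6-phosphate dehydrogenase), and solve growth-then-product:

```r
library(fbascreen)

m  <- build_core_model() |>
  add_3hp_pathway() |>
  set_condition(condition(gur = 15, our = 10))   # mmol/(gDC h)

km  <- apply_knockout(m, c("tpiA", "zwf"))
sol <- solve_lexicographic(km, secondary = "EX_3hp_e")
yield_table(sol, km)
#> Yield report (basis: consumed glycerol 15 mmol/(gDC h))
#>   growth rate     0.6334 1/h
#>   biomass           56.3 C-mol%
#>   3hp              32.5 C-mol%
#>   13pdo             0.0 C-mol%
#>   acetate           0.0 C-mol%
#>   succinate         0.0 C-mol%
#>   lactate           0.0 C-mol%
#>   ethanol           0.0 C-mol%
#>   formate           0.0 C-mol%
#>   carbon closure (incl. CO2): 100.0 C-mol%
```

Deleting the isomerase strands dihydroxyacetone phosphate; with the
Entner–Doudoroff entry also blocked by Δ*zwf*, carbon is forced through
the normally latent methylglyoxal shunt to pyruvate, growth drops to
63% of wild-type, and a third of the consumed glycerol carbon leaves as
3HP (wild-type secretes essentially none). The carbon closure row is an
internal audit: all consumed carbon is accounted for by products, CO2
and biomass.

The exhaustive double-knockout screen recovers the same design:

```r
double_knockout_screen(m,
  genes = c("tpiA", "zwf", "pgi", "edd", "gldA", "fsaB", "yqhD", "mgsA"),
  top_k = 5)[, c(1, 2, 4, 6)]
#>   gene_1 gene_2 relative_growth_pct threehp_yield_cmol_pct
#> 1   tpiA    zwf               63.34                  32.51
#> 2   gldA   tpiA               63.34                  32.51
#> 3    pgi   tpiA               63.34                  32.51
#> 4   fsaB   tpiA               63.34                  32.51
#> 5    edd   tpiA               65.37                  30.52
```

Every top pair couples Δ*tpiA* with a block of an alternative glycerol
catabolic route — the same design logic found for the genome-scale
model, where Δ*tpiA* Δ*zwf* is the canonical choice. The same calls
accept a genome-scale model via `load_model("iAF1260.json")`.

`run_pipeline(run_config(...))` chains load → extend → condition →
knockout → solve → report and writes `fluxes.tsv`, `yields.json`,
`screen.tsv` and `run.log`.

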
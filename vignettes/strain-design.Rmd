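---
title: "Designing 3HP-producing E. coli strains by constraint-based modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing 3HP-producing E. coli strains by constraint-based modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbascreen)
```

## The model and its assumptions

`fbascreen` implements flux balance analysis (FBA) for strain design.
A metabolic network with stoichiometric matrix $S$ (metabolites ×
reactions) is assumed to operate at pseudo-steady state, so any flux
vector $v$ must satisfy $S v = 0$ within per-reaction bounds
$v_{\min} \le v \le v_{\max}$. Among the feasible fluxes, the cell is
assumed to maximize its growth rate $\mu$ — the flux through a lumped
biomass reaction:

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \;
  v_{\min} \le v \le v_{\max}.$$

Three standard caveats apply and carry over to everything the package
computes: FBA knows nothing of enzyme kinetics, allosteric regulation
or expression levels; the optimal flux vector is generally not unique
even when the optimal objective is; and "growth maximization" is a
hypothesis about evolved wild-type physiology that transfers only
approximately to freshly engineered knockouts.

### Two-stage (lexicographic) optimization

At the growth optimum a production flux is typically undetermined: many
flux vectors achieve the same $\mu^\ast$ with different product
secretion. `solve_lexicographic()` therefore solves twice — first for
$\mu^\ast$, then for the maximal product flux subject to
$v_{\text{biomass}} \ge \mu^\ast (1 - 10^{-6})$. The reported product
flux is thus the *best case compatible with maximal growth*, a
deliberate optimistic convention for screening. The $10^{-6}$ relative
relaxation replaces an exact equality because pinning a variable at a
floating-point optimum makes the second LP infeasible on some
instances; its visible consequence is that a "zero" product flux is
reported as a value of order $10^{-5}$ (the relaxation frees that
sliver of substrate), which table writers round to 0 at the $10^{-7}$
flux threshold.

### The LP solver

The package ships its own bounded-variable two-phase revised simplex
(`simplex_bounded()`). FBA instances are small by LP standards but
highly degenerate — many ties, many free reversible columns — and the
solver is built for robustness over speed: the basis is re-factorized
every iteration, Dantzig pricing switches to Bland's rule when the
objective stalls, and feasibility is enforced at $10^{-9}$ with a
returned-solution audit of $\max |S v| < 10^{-6}$. Optimal objective
values are cross-checked in the test suite against an independently
formulated LP solved by an external interior-point/simplex
implementation (scipy's HiGHS), with agreement required to $10^{-6}$.

## The production pathway

Seven reactions turn a host model into the producer
(`add_3hp_pathway()`), shipped as a data file so the stoichiometry can
be swapped without code changes:

| reaction | stoichiometry |
|---|---|
| glycerol dehydratase (*dhaB·gdrAB*) | glycerol → 3HPA + H₂O |
| 3HPA dehydrogenase (*aldH*) | 3HPA + NAD⁺ + H₂O → 3HP⁻ + NADH + 2 H⁺ |
| 3HP transporter | 3HP⁻ + H⁺ → 3HP⁻[e] + H⁺[e] (proton symport) |
| 3HP exchange | 3HP[e] → |
| 1,3-PDO oxidoreductase (*yqhD*) | 3HPA + NADPH + H⁺ → 1,3-PDO + NADP⁺ |
| 1,3-PDO transporter | 1,3-PDO ↔ 1,3-PDO[e] (diffusion) |
| 1,3-PDO exchange | 1,3-PDO[e] → |

Design choices here: 3HP is modeled as the −1 anion with a compensating
proton in the symport, following the convention genome-scale E. coli
models use for lactate (the closest native analogue, whose transporter
the symport mimics); export steps are irreversible; the dehydratase and
dehydrogenase carry pseudo-genes identifying the plasmid-borne pathway,
which knockout screens exclude by default — deleting the product
pathway is never a useful design — while *yqhD*, a host gene, remains
screenable. All non-boundary pathway reactions pass the elemental
balance audit for C, H and O.

## Culture condition

`set_condition(model, condition(gur, our))` encodes glycerol-limited
microaerobic growth: glycerol exchange lower bound $-\mathrm{GUR}$,
oxygen lower bound $-\mathrm{OUR}$ (defaults 15 and 10 mmol/(gDC·h),
i.e. OUR/GUR = 0.67), every other carbon-bearing exchange closed to
uptake, and carbon-free inorganics plus CO₂ left free in both
directions. The uptake bound is an *upper limit on uptake*, not an
equality: the LP takes less substrate when that is optimal, and all
yields are computed on the uptake actually realized, which makes the
bound-vs-equality choice immaterial to C-mol% results.

## Knockouts and screening

Gene deletions act through boolean gene–protein–reaction rules: `and`
joins complex subunits, `or` joins isozymes, and a reaction whose rule
evaluates false under the deletion has both bounds set to zero
(`apply_knockout()`). Reactions with empty rules (spontaneous,
boundary, lumped) are non-deletable.

`double_knockout_screen()` evaluates all unordered pairs, de-duplicated
by their disabled-reaction sets first — two deletions hitting the same
reactions are provably the same LP, so each equivalence class is solved
once. Ranking is by 3HP yield, then relative growth, then gene ids, so
the output order is fully deterministic. Records report growth rate,
growth relative to wild-type, product flux and C-mol% yield; lethal or
infeasible deletions become records with zero growth and yield rather
than errors.

Carbon-molar yield uses carbon counts parsed from metabolite formulas —
never hard-coded — so glycerol contributes 3 carbons, acetate 2,
succinate 4, and so on automatically:

$$\mathrm{C\text{-}mol\%} =
  100\,\frac{v_{\mathrm{product}}\cdot n_C^{\mathrm{product}}}
            {v_{\mathrm{substrate}}\cdot n_C^{\mathrm{substrate}}}.$$

Biomass yield uses the net carbon drained by the biomass equation
(`net_biomass_carbon()`, mmol C/gDC; cycling cofactors cancel), and
every reported yield table closes its carbon balance to 100 ± 0.1
C-mol% including CO₂ and biomass — an end-to-end audit of
stoichiometry, solver and accounting at once.

## The reduced host model

`build_core_model()` generates a ~50-reaction central-carbon *E. coli*
model so the full pipeline is testable with no downloads. It emulates
the topology that matters for glycerol-based 3HP design:

* both glycerol routes — glycerol kinase (ATP-consuming) feeding the
  aerobic G3P dehydrogenase, and glycerol dehydrogenase feeding the
  PEP-dependent dihydroxyacetone kinase;
* the *tpiA* isomerase linking DHAP to lower glycolysis; the
  gluconeogenic FBP arm up to G6P; the oxidative PPP entry (*zwf*) with
  Entner–Doudoroff (*edd*/*eda*) and a lumped non-oxidative return;
  fructose-6-phosphate aldolase (*fsaB*), which closes the
  DHA-recycling ED cycle that keeps a Δ*tpiA* strain alive;
* the methylglyoxal shunt (*mgsA*, glyoxalase route to D-lactate,
  reversible D-LDH) — the normally latent DHAP → pyruvate bypass that
  becomes the sole catabolic route in a Δ*tpiA* Δ*zwf* strain;
* pyruvate dehydrogenase (an `and` complex) and formate lyase, lumped
  TCA, acetate (an `or` isozyme pair), ethanol, lactate and succinate
  branches, lumped respiration, transhydrogenase, ATP maintenance, and
  a single-precursor biomass drain.

Every metabolite carries its real formula and charge; every
non-boundary reaction balances C, H, O, N, P, S *and* charge, so
mass-balance tests on the fixture are meaningful chemistry, not
bookkeeping. Generation is deterministic — identical specs dump to
byte-identical JSON.

Parameter defaults, chosen once on physiological grounds: P/O ratio 1.5
ATP/NADH (mid-range for *E. coli* respiration on glycerol),
growth-associated ATP demand 8.39 mmol/gDC, biomass carbon 40 mmol
C/gDC (≈0.48 g carbon per g dry cell). The precursor drain (10
pyruvate + 5 acetyl-CoA per gDC) costs 45 mmol C/gDC including the
CO₂ lost at pyruvate dehydrogenase, so at GUR 15 the wild-type optimum
is exactly carbon-limited at μ = 1.0 h⁻¹ — a convenient, legible
reference point. ATP maintenance is present but not forced (lower
bound 0), consistent with keeping host-model defaults untouched.

### What the fixture shows — and does not

On this model the package reproduces the *mechanistic* design logic:
single knockouts never open 3HP production; pairing Δ*tpiA* with a
block of the alternative catabolic routes (Δ*zwf*, Δ*pgi*, Δ*edd*,
Δ*gldA*, Δ*fsaB*) forces flux through methylglyoxal synthase (ED flux
exactly 0), costs ~37% of growth, and sends ~32% of consumed carbon to
3HP; with growth forced to zero and oxygen unlimited the 3HP ceiling
is exactly 100 C-mol%, because glycerol → 3HPA → 3HP conserves all
three carbons and only requires reoxidizing one NADH. The *numbers*
(32.5 C-mol%, 63% relative growth) are properties of the reduced
network — its lumped respiration, single-precursor biomass and absent
amino-acid metabolism — and are not expected to match genome-scale
values (70.5 C-mol%, 48%); tests that pass on the fixture validate the
machinery and the mechanism, not genome-scale quantities. The
genome-scale validation tests run only when a locally supplied iAF1260
file is present, since the published model must be fetched from the
BiGG database.

## Numerical conventions

* Feasibility tolerance $10^{-9}$; steady-state audit $10^{-6}$;
  fluxes below $10^{-7}$ written as 0 in human-readable tables.
* Infinite bounds are clamped to $\pm 10^5$ (constraint-based models
  conventionally use $\pm 1000$ already).
* Stage-2 biomass pin: relative relaxation $10^{-6}$ (see above).
* Matrix indexing is input-order and stable, so permuting reactions
  changes nothing but column order and two runs of any screen are
  identical.
* Ties in screen rankings are broken by relative growth, then
  lexicographic gene ids.

## Problem sizes used in tests and the acceptance script

All shipped computations run on the reduced model: ~60 reactions after
pathway grafting, single screens over 8 genes, double screens over the
28 pairs of the 8-gene design set, and a 9-point OUR sweep — a few
hundred LP solves in total, a few seconds end to end. Screens over
genome-scale models use the same code path with the equivalence-class
deduplication doing proportionally more work; an all-pairs screen of a
1260-gene model (~800k pairs) is a cluster job, not a desk job, which
is why screens accept an explicit `genes` subset.

## Known limitations

* No flux variability analysis, MOMA/ROOM or parsimonious FBA; the
  lexicographic second stage is the only degeneracy treatment.
* No kinetic or regulatory layer: methylglyoxal toxicity, dhaB
  coenzyme-B12 dependence and expression burden — all of which matter
  in vivo — are invisible to FBA.
* The SBML reader covers Level 3 + FBC v2 as used by current model
  distributions (flux-bound parameters, gene-product associations,
  formulas in `fbc:chemicalFormula` or legacy notes), not the full
  SBML specification.
* Charge balance is audited but advisory; published genome-scale
  models contain known charge inconsistencies.
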
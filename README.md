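# robustfba

Constraint-based analysis of **metabolic robustness** in genome-scale
models (GSMs), motivated by photoautotroph (polar diatom) metabolism.
The package answers two questions about a stoichiometric model
`S v = 0, lb ≤ v ≤ ub` with a biomass objective:

* how sensitive is the predicted growth rate to the **biochemical
  composition parameters** that define the biomass reaction and the
  nutrient uptake bounds (local one-at-a-time scans, random and
  exhaustive multiplier combinations, Morris elementary-effects
  screening), and
* how robust are growth and the flux state to **structural
  perturbations** — single reaction and single gene deletions — and by
  which compensatory pathways is robustness achieved?

## Methods at the core

* **Parsimonious FBA**: lexicographic `max μ`, then `min Σ|vᵢ|` at fixed
  optimal growth (Manhattan norm via forward/reverse flux splitting),
  modelling minimal enzyme usage and selecting a single flux state.
* **MOMA**: `min Σ(vᵢ − wᵢ)²` over the perturbed model's constraints
  against the intact-model reference `w` — short-term acclimation; the
  biomass flux of the minimiser is the growth estimate.
* **Deletion classification**: robust (growth change ≤ 1 %),
  intermediate, essential (growth below the 10⁻⁶ h⁻¹ detection limit;
  fluxes below 10⁻⁹ count as zero elsewhere), with compensatory
  accounting (reactions activated vs inactivated, pathway flags) and a
  photon-uptake window `[w/1.5, 1.5 w]` to keep light harvesting
  realistic under deletions.
* **Gene level**: boolean gene-protein-reaction (GPR) rules with OR
  (isozymes / divergent alleles) and AND (complexes); divergent allelic
  variants are added as redundant OR partners.
* **Network view**: directed bipartite metabolite–reaction graph of the
  active subnetwork; degrees, raw betweenness, reciprocal-sum closeness;
  comparison of metabolites of robust vs sensitive reactions.
* **Biomass builder**: 69 named composition parameters → mass-normalised
  component equations (1 g of monomers per flux unit) and renormalised
  component fractions (unit biomass flux consumes 1 gDW) plus C:N / N:P
  uptake cascades.

LPs are solved by a bundled bounded-variable primal simplex (C++);
quadratic programs via `quadprog`. Models are read and written as SBML
Level 3 + `fbc` or a COBRA-style JSON dialect. A deterministic synthetic
model generator (with brute-force deletion ground truth and elemental
balancing) makes every stage testable offline.

## Worked example

```r
library(robustfba)

gen <- generate_model(synth_config(seed = 1, composition = "full"))
gen$model
#> metabolic model 'synth_full_seed1'
#>   124 reactions, 115 metabolites, 109 genes, 109 gene-reaction associations
#>   4 compartments: e, c, h, m
#>   objective: BIOMASS

sol <- solve_pfba(gen$model)
sol
#> flux solution (pfba), status: optimal
#>   growth: 0.0192582 h^-1 (0.4622 d^-1)
#>   Manhattan norm of fluxes: 27.9035
#>   96 of 124 reactions carry flux

local_sa(gen$model, gen$params, parameters = c("ps", "totalprot", "cn"))
#> local sensitivity analysis: 3 parameters, factor 40%
#>   largest growth responses:
#>     ps           up      +40.00%
#>     ps           down    -28.57%
#>     totalprot    up       +1.21%
#>     totalprot    down     -1.14%
#>     cn           up       +0.00%

scan <- single_reaction_deletion(gen$model, "fba", reference = sol)
summarize_robustness(scan)
#> reaction deletion scan (fba): 96 active targets
#>   robust          11  (11.5%)
#>   intermediate     2  (2.1%)
#>   essential       83  (86.5%)
```

Reading the output: the model grows at 0.46 d⁻¹ on a bicarbonate bound
of 0.78 mmol gDW⁻¹ h⁻¹ and is carbon-limited — a 40 % increase in the
carbon uptake rate raises growth by exactly 40 %, a 40 % decrease (×1/1.4)
lowers it by 28.6 %, while composition parameters move growth by ~1 %
because the biomass mass-normalisation buffers them. Of the 96 active
reactions, deleting 11 changes growth by at most 1 % (backed by dormant
alternative routes or isozymes, visible in the `n_activated` column of
the scan), while 83 abolish growth.

The full analysis — QC, pFBA, sensitivity, FBA and MOMA deletion scans
with and without divergent alleles, network metrics — runs as one call:

```r
res <- run_pipeline(run_config(synth = synth_config(seed = 1),
                               out_dir = "results/run1"))
```

which writes TSV/JSON outputs plus a manifest (seed, tolerances,
versions). `vignettes/metabolic-robustness.Rmd` documents the model,
assumptions, parameter meanings and design choices.

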
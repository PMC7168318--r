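---
title: "Metabolic robustness analysis with robustfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic robustness analysis with robustfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustfba)
```

## The question the package answers

Genome-scale metabolic models (GSMs) describe a cell as a stoichiometric
network: a matrix $S$ (metabolites $\times$ reactions) with flux bounds
$l \le v \le u$ and a biomass reaction whose flux is the growth rate
$\mu$ (h$^{-1}$). `robustfba` asks how *robust* the predicted growth and
flux state of such a model — motivated by photoautotroph (polar diatom)
metabolism — is to two kinds of perturbation:

* **parametric**: changes in the biochemical composition parameters that
  define the biomass reaction and the nutrient-uptake bounds, and
* **structural**: removal of single reactions or single genes from the
  network.

## Flux computations

**Parsimonious FBA** (`solve_pfba()`) is a lexicographic two-step
optimisation over the steady-state polytope $\{v : Sv = 0,\ l \le v \le
u\}$. Step one maximises the biomass flux; step two pins the biomass flux
at its optimum $\mu^\*$ (as an equality: growth is treated as exactly
optimal, not as a fraction of the optimum) and minimises the Manhattan
norm $\sum_i |v_i|$ by splitting each flux into nonnegative forward and
reverse parts. The secondary objective models minimal total enzyme usage
and selects one flux distribution among alternative growth optima. True
degeneracy can survive even the second objective, so flux-level outputs
(active-set counts, network sizes) are guaranteed reproducible only for a
fixed solver; the bundled simplex is deterministic, and all stochastic
stages consume one integer seed.

**MOMA** (`solve_moma()`) models short-term acclimation after a
perturbation: it minimises $\sum_i (v_i - w_i)^2$ over the perturbed
model's constraints, where $w$ is the intact-model reference flux vector.
Growth is read off the biomass flux of the minimiser — it is not itself
optimised — so MOMA growth never exceeds the re-optimised (FBA) growth
for the same deletion. The distance is taken over all reactions,
exchanges included, following the common COBRA convention.

**Solvers.** The LPs are solved by a bounded-variable two-phase primal
simplex implemented in C++ (`src/simplex.cpp`): the models this package
targets (hundreds of reactions) are far below the size where sparse
interior-point machinery pays off, and a self-contained dense simplex
keeps the package dependency-free at the optimisation layer. It is
validated in the test suite against exhaustive vertex enumeration of the
flux polytope and against an independent COBRA implementation on an
exported fixture. The MOMA quadratic program goes through
`quadprog::solve.QP` after eliminating fixed variables and
rank-filtering the equality rows.

**Detection limits.** A flux is "active" above $10^{-9}$ mmol gDW$^{-1}$
h$^{-1}$; the objective flux uses a looser limit of $10^{-6}$ h$^{-1}$
(`solver_settings()`). Deletions whose LP/QP is infeasible are assigned
growth 0.

## Quality control

Two standard checks guard against reconstruction errors
(`qc_energy_from_nothing()`, `qc_leak_test()`): with all exchange
reactions closed (and, separately, with only the carbon and light inputs
closed) the maximal flux through the ATP maintenance reaction and
through a temporary NADPH $\to$ NADP$^+$ + H$^+$ drain must stay below
the detection limit, and no metabolite may be net-producible (checked
with one aggregate LP over bounded demand reactions, then per-metabolite
LPs to localise offenders). An infeasible closed model — e.g. one with a
forced maintenance flux and no internal energy source — can produce
nothing and passes. The pipeline refuses to continue past a failing QC
unless forced.

## Biomass from 69 composition parameters

The biomass reaction is assembled from 69 named parameters (five
pigments in pg/cell; GC proportion, genome size and RNA:DNA ratio; 19
lipid species and 9 sugars in mol/gDW; 20 amino acids and six
macromolecular totals in g/gDW; glucan and triacylglycerol storage
proportions; C:N and N:P molar ratios; the carbon uptake rate in mmol
gDW$^{-1}$ h$^{-1}$; carbon and dry weight per cell). Within each
macromolecular component the monomer coefficients are normalised so one
flux unit consumes exactly 1 g of monomers (checked to $10^{-6}$
relative), and the six component totals — which as printed sum to 1.0262
g/gDW — are renormalised to sum to exactly 1 so that unit biomass flux
consumes 1 gDW of precursors. This normalisation is itself the main
mechanism of parametric robustness: uniformly scaling all monomers of
one component cancels exactly, and single-monomer changes only shift the
mixture within that component.

Three parameters never enter any equation and therefore have exactly
zero sensitivity: genome size and the RNA:DNA ratio (redundant with the
measured total DNA and RNA masses, which are used directly) and carbon
per cell (its information enters through the dry weight per cell used to
convert pigment units). Keeping them in the registry preserves the full
69-parameter interface and makes the null sensitivity of redundant
descriptors an explicit, testable prediction.

DNA base composition follows the GC proportion (G = C = GC/2,
A = T = (100−GC)/2 of bases; RNA analogously with uracil). Per-cell
pigment masses are converted to g/gDW through the dry weight per cell.
Glucan (30% of carbohydrate) and TAG (20% of lipid) are carbon-storage
sub-components inside the carbohydrate and lipid equations, with their
coefficients tracked separately so a storage production flux can be
reported. Polymerisation ATP costs per mmol of monomer (4.3 protein, 2.4
RNA, 3.4 DNA, 1.0 carbohydrate and lipid) and 30 mmol gDW$^{-1}$
growth-associated maintenance follow template photoautotroph
reconstructions and are held fixed; they are conventions, not fitted
quantities.

Uptake constraints cascade from three parameters: the bicarbonate bound
equals the carbon uptake rate $P_s$, the nitrogen bound $P_s/(C{:}N)$,
the phosphorus bound $N/(N{:}P)$ — upper limits on the uptake direction.

## Sensitivity analyses

"Change by 40%" is implemented multiplicatively: up is $\times 1.4$,
down is $\times 1/1.4$. The reason is consistency of the whole analysis:
growth is proportional to the carbon-uptake bound whenever carbon is the
unique binding constraint, so a 40% perturbation must produce a +40% /
−28.6% growth response pair, which is what one-at-a-time scans of this
package print (`local_sa()`); the additive reading ($\times 0.6$) is
available via `symmetric = TRUE`. Random combinations
(`random_combo_sa()`) draw each multiplier independently from the
two-point set $\{1/1.4, 1.4\}$ (a uniform-interval alternative sits
behind `uniform = TRUE`); exhaustive combinations
(`exhaustive_combo_sa()`) enumerate all $2^k$ corners for $k \le 12$
parameters.

Morris elementary-effects screening (`morris_sa()`) uses a $p = 4$ level
grid with step $\Delta = p/(2(p-1)) = 2/3$ on the unit cube,
latin-hypercube-sampled trajectory starts (`lhs`), and $r$ trajectories
of $k+1$ model evaluations. Effects are computed on the unit-scaled cube
so indices are comparable across parameters with different units — the
cube maps linearly onto $[\theta/1.4,\ 1.4\,\theta]$ per parameter. On a
linear function the design recovers the coefficients exactly with zero
effect variance, which the suite asserts. With the default budget of
6500 evaluations and $k = 69$, $r = \lfloor 6500/70 \rfloor = 92$; the
acceptance script uses $r = 10$ (700 evaluations), which is ample to
rank a screening problem whose answer is dominated by one parameter.

## Deletion scans and classification

Single reaction deletions (`single_reaction_deletion()`) set the
target's bounds to $[0,0]$; single gene deletions
(`single_gene_deletion()`) disable every reaction whose
gene-protein-reaction (GPR) boolean rule evaluates false under the
knockout (OR = isozymes or redundant alleles, AND = complex subunits;
the empty rule never disables). Before each scan the photon uptake flux
is constrained to $[w/1.5,\ 1.5\,w]$ around its intact-model value $w$,
preventing unrealistically large light-harvesting responses. The
modified model is solved either by re-optimised parsimonious FBA
(long-term acclimation; pFBA rather than plain FBA so that active-set
comparisons are well defined) or by MOMA against one global intact-model
reference. Deleting a reaction that carries no reference flux cannot
change the optimum, so inactive targets are reported as trivially robust
without re-solving; the brute-force oracle (`brute_force_deletions()`)
re-solves everything and the suite checks the shortcut against it on 20
seeded models.

Classification by growth ratio $\mu_{del}/\mu_{wt}$: **robust** when
$|1-\text{ratio}| \le 0.01$, **essential** when $\mu_{del}$ is below the
objective detection limit, **intermediate** otherwise. Inhibition
$\ge 99\%$ with detectable growth is flagged `near_essential` — an
internal fourth bin kept separate so the strict definition of essential
(no detectable growth) is preserved, and merged with essential in the
headline percentages. A deletion can relax a constraint (removing a
forced maintenance flux), so growth ratios may exceed 1 by a small
margin; such targets classify as robust.

Divergent allelic variants are modelled by `augment_with_alleles()`:
each leaf occurrence of a paired gene $g$ becomes $(g\ \mathrm{OR}\
a)$, which can only preserve or increase gene-level robustness — a
monotonicity the suite asserts across seeds. Scans after augmentation
still iterate over the original gene list so percentages with and
without alleles share a denominator; "active genes" are genes appearing
in the GPR of at least one active reaction.

Compensatory responses (`compensatory_response()`) compare active sets
between the intact and modified models (activated = inactive $\to$
active) and flag tagged pathways (photorespiration, Mehler, PTOX, cyclic
PSI, mitochondrial ATP, photon uptake, chloroplast ATP) as activated or
increased by their summed absolute flux.

## The bipartite network view

`build_active_bipartite()` turns the active subnetwork of a solution
into a directed two-mode graph: substrates point to reactions, reactions
to products, with substrate/product roles swapped for reactions carried
at negative flux — orientation follows the realised flux direction.
Metabolite degrees count incident reactions (in = producing, out =
consuming). Betweenness is the raw, unnormalised count of directed
shortest paths through a node (paths traverse metabolite and reaction
nodes alike; metabolite rows are reported); closeness is the reciprocal
sum of outgoing shortest-path lengths to reachable nodes, 0 when nothing
is reachable. Outgoing distances are one of two defensible directed
conventions; it is the one used here and stated so results are
interpretable. `compare_metabolite_sets()` contrasts the metabolites
incident to robust versus sensitive reactions (sets may overlap —
currency metabolites inevitably belong to both) by mean/median of each
metric plus relative-frequency degree histograms binned 1..20 and 20+.

## The synthetic model generator

`generate_model()` builds deterministic toy photoautotroph models that
exercise every analysis without any external file: exchange reactions
for bicarbonate, nitrate, phosphate and photons; linear electron flow
producing NADPH and ATP at a fixed 2 NADPH : 2.57 ATP : 8 photons
stoichiometry; a cyclic flow around PSI at 2 photons/ATP; carbon
fixation (3 ATP + 2 NADPH per carbon); nitrate reduction; a
two-leg organelle redox shuttle through a malate/oxaloacetate-like
carrier feeding mitochondrial oxidative phosphorylation at an effective
P/O of 1.5 (the low end of measured effective ratios); an alternative
oxidase; and dissipation reactions (photorespiration, Mehler, PTOX)
that optimal solutions leave inactive. With these choices the
parsimonious control solution covers the ATP:NADPH deficit with cyclic
PSI and keeps the longer mitochondrial route dormant, so structural
perturbations exhibit the compensatory-activation signature the
analyses are designed to detect: closing the shuttle
(`bioenergetics_scenario("no_redox_exchange")`) leaves the cyclic route
carrying the balancing ATP, while coupling PSI electron transfer to
mitochondrial ATP generation (`"psi_coupled"`, which closes AOX and the
cyclic flow) relocates the same ATP production to the mitochondrion at
identical growth.

Biomass is assembled by the biomass module itself, either from the full
69-parameter monomer set ("full", ~116 reactions) or from one generic
monomer per component ("compact", ~60 reactions, used for the
brute-force comparisons); a "chain" mode gives a minimal
uptake-to-biomass model. Monomers carry real small-molecule formulas
restricted to C/H/N/O/P (sulfur-bearing monomers get oxygen-substituted
surrogates), and every internal reaction is balanced elementally with
water and protons as balancing species — so generated models are
leak-free by construction, which is still re-verified by both QC checks
before a model is returned. Dormant alternative synthesis routes are
two-step (one intermediate), i.e. costlier in Manhattan norm than the
one-step primaries, so parsimonious FBA leaves them inactive until a
deletion forces a reroute; GPR structure (two-gene OR isozymes, two-gene
AND complexes, single-gene rules) and the divergent-allele pair table
are sampled deterministically from the seed.

At the nominal composition the generated "full" model grows at 0.46
d$^{-1}$ on a bicarbonate bound of 0.78 mmol gDW$^{-1}$ h$^{-1}$ —
growth is carbon-limited with roughly 1.3-fold slack in the nitrogen
bound at C:N 5.7, so the carbon uptake rate is by far the dominant
parameter.

**What the generator does not emulate.** Real genome-scale
reconstructions are one to two orders of magnitude larger, with far
higher redundancy (most reactions inactive under any one condition),
currency-metabolite hubs of degree in the hundreds, thermodynamic
irreversibilities curated per reaction, and biomass equations inherited
from measured macromolecular chemistry. Passing tests on synthetic
models therefore demonstrates correctness of the algorithms and the
classification logic under controlled ground truth — not that any
particular published robustness percentage will be reproduced on a real
reconstruction, where active fractions and class proportions depend on
network redundancy the generator only sketches.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything on the
synthetic models: brute-force versus optimised deletion scans on 20
seeded compact models, vertex-enumeration oracles on networks of up to
8 reactions, 5,000 random parameter combinations, Morris screening with
700 evaluations, and full reaction/gene scans under both FBA and MOMA
on the full model — sizes chosen so the whole analysis reruns in
minutes on one CPU while still exercising each code path at meaningful
scale. Ties in the simplex are broken deterministically (Dantzig
pricing with a Bland fallback under degeneracy); LP feasibility is
enforced to $10^{-9}$ and re-verified at $10^{-6}$ on every returned
solution; equality systems passed to the QP are rank-filtered by QR
with explicit consistency checks for dropped rows.

## Known limitations

Growth optimality and minimal flux are hypotheses, not laws; MOMA's
single global reference is one convention (per-deletion references
would differ); regulatory effects, light physiology and futile cycles
are outside the model class; betweenness on the bipartite graph mixes
metabolite and reaction nodes on the path interior by construction; and
the bundled dense simplex targets models of at most a few thousand
reactions — beyond that a sparse external solver would be the right
tool.
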
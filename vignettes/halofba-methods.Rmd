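---
title: "Constraint-based analysis of salinity-dependent metabolism with halofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of salinity-dependent metabolism with halofba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halofba)
```

## The modeling problem

Halophilic bacteria that accumulate compatible solutes — ectoine and
hydroxyectoine above all — pay a growth-coupled metabolic tax that rises
with external salinity: solute synthesis drains TCA-cycle intermediates
(oxaloacetate, acetyl-CoA) and ATP, so the whole central carbon and
energy metabolism must re-balance when salt goes up. `halofba`
implements the constraint-based workflow used to study this
re-balancing on a genome-scale metabolic model (GEM): two
salinity-specific biomass formulations, flux balance analysis (FBA) and
its screens, dead-end diagnostics, uniform sampling of the steady-state
flux space, and statistical comparison of the sampled flux
distributions between a low- and a high-salinity condition.

The model is the data. A `metabolic_model` holds metabolites with
bracketed compartment suffixes (`glc-d[c]` for cytoplasm, `[p]`
periplasm, `[e]` extracellular), reactions with bounds in
mmol gDW^-1 h^-1, gene–protein–reaction (GPR) boolean rules (`and` =
enzyme complex, `or` = isozymes), and an objective reaction. At steady
state the stoichiometric matrix S and flux vector v satisfy S·v = 0;
bounds encode reversibility (default −1000/1000), irreversibility
(lower bound 0) and the medium. Exchange reactions are outward
positive: glucose supplied at 10 mmol gDW^-1 h^-1 is a lower bound of
−10 on its exchange.

## Condition-specific biomass and maintenance

Growth is represented by a biomass pseudo-reaction draining precursors
in growth-proportional amounts; its flux is the specific growth rate
(h^-1). Two formulations differ between salinities:

* **Macromolecule groups.** Each group with mass fraction f (g gDW^-1)
  and monomer molar ratios r contributes monomer coefficients
  −(f / Σ r·w)·r, where w are monomer weights in g mmol^-1 — so each
  group drains exactly f grams per gram of new biomass
  (`assemble_biomass_reaction()`).
* **Growth-associated maintenance (GAM).** ATP + H2O → ADP + Pi + H
  with coefficient `compute_gam(base, polymerization_cost)`. The base
  cost is 36.94 mmol gDW^-1 and the polymerization cost is
  condition-specific (23.04 at low, 8.79 at high salinity, reflecting
  the compositional shift), giving 59.98 and 45.73 mmol gDW^-1. The
  inputs carry two decimals, so the sum is done in integer hundredths —
  reports never show float drift.
* **Osmolyte demand.** Ectoine-like solutes are growth-associated, so
  they appear directly in the biomass reaction with condition-specific
  coefficients — the structural difference that makes high-salinity
  growth expensive.
* **Non-growth maintenance (NGAM).** A fixed ATP-hydrolysis flux
  (default 7.6 mmol gDW^-1 h^-1) applied as an equality by
  `apply_condition()`: upkeep is not optional, so it is a pinned drain
  rather than a lower bound.

Monomer ratios can be derived from sequence data:
`amino_acid_ratios_from_proteome()` assumes equal expression of all
coding sequences, and `dnt_ratios_from_gc()` applies strand symmetry to
the genomic G+C content. Where organism-specific measurements are
missing, `template_biomass()` supplies a literature-style fallback
composition whose values are flagged `template = TRUE` so downstream
reports can distinguish template from measurement.

## The LP core and its preprocessing

All flux questions reduce to `max c'v` subject to `S v = 0`,
`lb ≤ v ≤ ub`. The solver behind `fba()` is the two-phase simplex from
the recommended `boot` package, behind two preprocessing steps that we
found necessary for robustness:

1. Variables pinned by equal bounds are substituted out before solving.
2. The equality system is row-reduced to an independent, consistent
   subset. Conservation relations (ATP/ADP, NAD/NADH pools) always make
   rows of S linearly dependent, and redundant equalities derail the
   textbook simplex.

Solutions are post-validated at 1e-6 (balance and bounds); only the
objective value is treated as canonical, because at degenerate optima
many flux vectors achieve it and the returned vertex is arbitrary.
"No growth" means an optimum below 1e-6 h^-1 — deliberately far below
any biologically meaningful rate and far above solver noise.

On top of the core sit the screens: `screen_carbon_sources()` (close
all candidates, open one at −10, maximize growth),
`single_gene_deletions()` (GPR propagation: a reaction closes only if
its rule evaluates false with the gene removed, so isozymes rescue and
complexes break), and `atp_yield_per_substrate()` (biomass pinned to
zero, substrate pinned, maintenance relaxed and maximized). We
implement gene deletion followed by GPR propagation rather than direct
reaction deletion; with complexes and isozymes present the two differ,
and propagation is the biologically meaningful variant.

## Dead ends and blocked metabolites

`root_gaps()` is a sign scan: after splitting every reversible reaction
into two directions, a metabolite whose occurrences are all negative
can never be produced; all positive, never consumed. The split makes
the sign logic unambiguous. `blocked_metabolites()` then probes actual
flux capacity metabolite by metabolite: a temporary sink (or source) is
added, all exchanges are opened, and its flux is maximized; an optimum
at zero (tol 1e-8) marks the metabolite blocked. Downstream/upstream
gap sets are the blocked sets minus the root sets. We use an LP per
metabolite rather than one monolithic mixed-integer program — the
blocked-set semantics are identical and the machinery much lighter.
Two mass-balance modes are reported: `strict` (S v = 0 everywhere) and
`relaxed` (every row may accumulate via its own slack). The strict mode
also flags conserved-moiety pools (ATP/ADP and the like) that no
boundary flux can fill or drain — a known, informative behaviour of
this test family rather than a defect.

## Sampling the flux polytope

FBA returns one optimal vertex; the space of *all* allowed flux states
is a bounded polytope, and comparing conditions distributionally
requires uniform samples from it.
`project_to_independent_variables()` row-reduces S (plus rows for
bound-pinned reactions, so the projection is affine) into pivot and
free coordinates: any assignment to the free coordinates reconstructs
a full steady-state vector exactly. Two samplers operate in that
projected space:

* `rejection_sample()` — the literal reference method: draw the free
  coordinates uniformly over their tight bounding box (each
  coordinate's achievable flux range, found by LP), back-calculate the
  dependent fluxes, keep the draw only if no bound is violated. Exact,
  but the acceptance rate collapses with dimension, so it is guarded
  to ≤ 6 dimensions and used as the oracle.
* `hit_and_run_sample()` — the production sampler: coordinate
  hit-and-run (a Gibbs walk), redrawing one free coordinate at a time
  uniformly from the exact interval the remaining constraints allow.
  Every iterate is feasible; the stationary law is uniform. Defaults:
  1000 warm-up updates, thinning 10, start at the average of the
  per-coordinate extreme flux vectors (feasible by convexity). The
  warm-up and thinning defaults are recorded in the returned object so
  results are auditable; on strongly elongated polytopes users should
  raise both (the tests compare the samplers where mixing is provably
  easy, at ≤ 3 dimensions).

Randomness comes from R's own generator with the user's integer seed
recorded in every sample set; a run is bitwise reproducible from
`(model, n, seed, warmup, thinning)`. Every returned point is asserted
to satisfy S·v = 0 within 1e-6 and the bounds within 1e-9 — the run
aborts otherwise. `median_fluxes()` reports column medians normalized
by the condition's glucose uptake, the scale on which flux maps are
drawn.

## Comparing conditions and correlation modules

`wilcoxon_compare()` screens each reaction with a two-sided rank-sum
test in the tie-corrected normal approximation, oriented so positive Z
means larger flux in the second (high-salinity) sample. The default
screen |Z| > 50 with p < 0.01 is deliberately extreme: at 20,000 points
per condition the largest achievable |Z| (complete separation) is about
sqrt(3n/2) ≈ 173, while null fluctuations are O(1), so anything passing
the screen is an unambiguous distributional shift and no further
multiple-testing correction is applied by default (Benjamini–Hochberg
q-values are emitted as an optional column). Effect sizes come from
`mean_paired_difference()`: 2000 points drawn without replacement from
each condition, subtracted, averaged. The marginals are independent
samples, so pairing is arbitrary and the estimator targets the
difference of marginal means; draws are made independently per
condition, with a seed, for reproducibility.

`spearman_matrix()` + `threshold_network()` build the correlated
reaction sets: rank correlation over sampled fluxes, edges at
|rho| ≥ 0.7 (ties at the threshold included), modules as connected
components of the thresholded graph. Components, not a community
algorithm, because the scientific claim being reproduced is about
cliques of stoichiometrically coupled reactions that either touch or
do not; a modularity-based option would add a tunable resolution
parameter without sharpening that claim. Flux columns pinned by the
constraints have no ranks to correlate and are excluded with a warning
rather than propagated as NaN edges. Networks export to GraphML, SIF
and TSV for standard viewers.

## The synthetic testbed

Real curated GEMs are large, hand-made artifacts; the package instead
tests every stage against small models whose truths are known by
construction (`make_toy_core_model()`):

* alternate glucose catabolism routes trading substrate-level ATP
  against NADH (the EMP/ED redox contrast), a lumped TCA-like
  oxidation loop, oxidative phosphorylation at P/O 2 plus an uncoupled
  NADH oxidase as redox valve;
* an ectoine-like osmolyte with synthesis (ATP-consuming) and
  degradation reactions forming a futile cycle, and biomass reactions
  `BIO_L`/`BIO_H` differing in osmolyte demand;
* GPR rules mixing a complex, an isozyme pair and single genes.

The generator computes the growth optimum in closed form from the
construction (best route, pyruvate and ATP balances), along with
forced flux couplings and the essential-gene set — independently of
the LP code these truths later test. `make_condition_pair()` adds the
salinity contrast: lower glucose uptake and a higher pinned
maintenance flux at high salinity (salt is energetically expensive),
which plants an exactly known between-condition shift in the
maintenance reaction for the comparison stage to recover. Default
conditions: glucose uptake 10 vs 6.5 mmol gDW^-1 h^-1, maintenance 7.6
vs 15.2 mmol gDW^-1 h^-1, osmolyte demand 0.1 vs 0.5 mmol gDW^-1 —
one doubling-scale contrast per axis, chosen once as a realistic
salinity contrast for this model family. A pleasing emergent check:
under those defaults the respiration genes become essential only at
high salinity, because substrate-level ATP alone can no longer cover
the raised maintenance — the same qualitative finding that motivates
salinity-dependent essentiality screens on real halophile models.

`make_ectoine_cycle_model()` builds n disconnected futile cycles
(within-cycle fluxes perfectly coupled, between-cycle fluxes
independent), the fixture for module recovery, and
`make_random_network()` grows random feasible networks around a
spanning pathway for oracle fuzzing (vertex-enumeration LP checks,
BFS-reachability gap checks, format round trips).

What the toys do not emulate: genome-scale dimensionality (thousands
of reactions), realistic cofactor multiplicity, thermodynamic
direction constraints, or measured biomass compositions. Passing tests
therefore certify the algorithms and their contracts, not the curation
quality of any particular reconstruction.

## Numerical choices

* LP feasibility requested at 1e-9; solutions validated at 1e-6.
* Row-reduction pivot tolerance 1e-10 (projection), 1e-9 (LP
  preprocessing).
* Blocked-metabolite capacity threshold 1e-8; no-growth threshold 1e-6
  h^-1.
* Sampler validity: balance 1e-6, bounds 1e-9, asserted per run.
* Degenerate polytopes (dimension 0) are handled as point masses, not
  errors; infeasible models abort with a diagnostic.
* Problem sizes in the shipped tests: toys of ≤ 20 reactions, 2000
  sample points per chain, 100-instance oracle sweeps — sizes at which
  the reference rejection sampler and the enumeration oracles are
  exact, chosen so the whole suite stays brisk on one core.

## Worked example

```{r example}
spec <- toy_spec(seed = 1)
toy <- make_toy_core_model(spec)
pair <- make_condition_pair(spec)
m_low <- apply_condition(toy$model, pair$low)
m_high <- apply_condition(toy$model, pair$high)
c(low = fba(m_low)$objective, high = fba(m_high)$objective)
pair$truth$growth
```

```{r essentiality}
cmp <- compare_essentiality(single_gene_deletions(m_low),
                            single_gene_deletions(m_high))
cmp$only_b # essential at high salinity only
```

```{r sampling}
s_low <- hit_and_run_sample(m_low, 2000, seed = 11, condition = "low")
s_high <- hit_and_run_sample(m_high, 2000, seed = 12,
                             condition = "high")
est <- mean_paired_difference(s_low, s_high, k = 2000, seed = 13)
est[["ATPM"]] # recovers the planted maintenance shift exactly
```

## Known limitations

* The SBML support is a pragmatic Level 3 subset (species, bounds as
  shared parameters, nested gene associations, one maximization
  objective, subsystem/kind in notes); exotic SBML constructs are out
  of scope, and the tabular dialect is the lossless interchange format.
* Coordinate hit-and-run mixes slowly on strongly elongated polytopes;
  diagnostics beyond the per-run validity assertions (e.g. effective
  sample size) are the user's responsibility.
* No flux variability analysis, MOMA/ROOM, double deletions, or
  expression-constrained variants; no thermodynamic consistency
  checking; no gap *filling* — gaps are reported, not repaired.
* Exact polytope volumes are not computed; sampling is the only
  characterization of the flux space offered.
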
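# halofba

Constraint-based analysis of salinity-dependent metabolism in
halophilic bacteria.

Ectoine-producing halophiles re-route their central carbon and energy
metabolism as external salinity changes, because compatible-solute
synthesis drains TCA intermediates and ATP in growth-coupled amounts.
`halofba` is an R toolkit for studying that re-routing on a
compartmentalized genome-scale metabolic model: it is aimed at systems
biologists who have (or simulate) a stoichiometric reconstruction with
two salinity-specific biomass formulations and want the full
constraint-based workflow — growth simulation, screens, dead-end
diagnostics, flux-space sampling, and between-condition statistics —
as tested, scriptable functions.

## What it computes

With stoichiometric matrix S (metabolites × reactions) and flux vector
v (mmol gDW⁻¹ h⁻¹), steady state imposes S·v = 0 and the environment
imposes lbᵢ ≤ vᵢ ≤ ubᵢ (exchanges outward positive: uptake is a
negative lower bound). On that polytope the package provides:

* **FBA** — `fba()` maximizes a biomass reaction's flux (= specific
  growth rate, h⁻¹) by LP; `screen_carbon_sources()`,
  `single_gene_deletions()` (GPR propagation: `and` = complex, `or` =
  isozymes) and `atp_yield_per_substrate()` build on it.
* **Condition-specific biomass** — `assemble_biomass_reaction()` turns
  macromolecule mass fractions + monomer ratios into a biomass
  equation; `compute_gam()` forms the growth-associated ATP
  maintenance as base + polymerization cost (36.94 + 23.04 = 59.98
  mmol gDW⁻¹ at low salinity, 36.94 + 8.79 = 45.73 at high), exact in
  integer hundredths.
* **Gap analysis** — `root_gaps()` (sign scan of S after splitting
  reversible reactions) and `blocked_metabolites()` (LP capacity test
  per metabolite, strict or accumulation-allowed mass balance).
* **Flux sampling** — `project_to_independent_variables()` projects
  the polytope to full dimension; `hit_and_run_sample()` (coordinate
  hit-and-run, production) and `rejection_sample()` (literal reference
  method, ≤ 6 dimensions) draw uniform flux samples;
  `median_fluxes()` normalizes by glucose uptake.
* **Condition comparison** — `wilcoxon_compare()` (tie-corrected
  rank-sum Z per reaction, screen |Z| > 50, p < 0.01) and
  `mean_paired_difference()` (2000-point random subtraction effect
  size).
* **Correlation networks** — `spearman_matrix()` +
  `threshold_network()` (edges at |ρ| ≥ 0.7, modules = connected
  components), with GraphML/SIF/TSV export.
* **Synthetic testbed** — `make_toy_core_model()` and friends generate
  toy networks (alternate glycolytic routes, TCA-like loop, ectoine
  futile cycle, complex/isozyme GPRs) whose optima, couplings,
  essential genes and module structure are known in closed form.

Models read and write a tabular dialect (`reactions.tsv` +
`metabolites.tsv`) and an SBML Level 3 subset with flux-bound and
gene-association annotations (`read_model()` / `write_model()`).

## Worked example

```r
library(halofba)

spec <- toy_spec(seed = 1)          # synthetic salinity study
toy  <- make_toy_core_model(spec)
pair <- make_condition_pair(spec)   # low vs high salinity conditions

m_low  <- apply_condition(toy$model, pair$low)
m_high <- apply_condition(toy$model, pair$high)
c(low = fba(m_low)$objective, high = fba(m_high)$objective)
#>      low     high
#> 1.980198 1.160766
```

Growth drops from 1.98 to 1.16 h⁻¹ at high salinity: uptake falls from
10 to 6.5 mmol gDW⁻¹ h⁻¹, the pinned maintenance flux doubles to 15.2,
and biomass demands five times more osmolyte. Both numbers equal the
generator's closed-form optima (`pair$truth$growth`) to 1e-8 — the LP
engine is continuously checked against construction-time truths.

```r
cmp <- compare_essentiality(single_gene_deletions(m_low),
                            single_gene_deletions(m_high))
cmp$only_b
#> [1] "g_ox"  "g_tca"
```

The respiration genes are essential *only* at high salinity: with
maintenance raised, substrate-level phosphorylation alone can no
longer pay the energy bill — salinity-dependent essentiality of
energy metabolism emerges from the constraints.

```r
s_low  <- hit_and_run_sample(m_low,  2000, seed = 11, condition = "low")
s_high <- hit_and_run_sample(m_high, 2000, seed = 12, condition = "high")
mean_paired_difference(s_low, s_high, k = 2000, seed = 13)[["ATPM"]]
#> [1] 7.6
```

The sampling-based effect size recovers the planted high-minus-low
maintenance shift of 7.6 mmol gDW⁻¹ h⁻¹ exactly, and
`threshold_network(spearman_matrix(s_low), 0.7)` resolves the model's
osmolyte cycles into independent correlation modules.

See `vignettes/halofba-methods.Rmd` for the model assumptions,
parameter meanings, numerical tolerances and design rationale.

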
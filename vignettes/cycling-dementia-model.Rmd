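---
title: "Modelling cycling infrastructure, physical activity and dementia lifetime costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cycling infrastructure, physical activity and dementia lifetime costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycledem)
library(dplyr)
```

## The model

`cycledem` implements a gender-stratified population model of how off-road
cycle lanes — cycling infrastructure physically separated from motor
traffic — change physical activity and, through the protective effect of
activity on dementia incidence, lifetime health and social care costs.
Off-road provision matters for the gender gap in particular: the published
effectiveness evidence shows substantially larger relative uptake
increases for women (40.3%–114.5%) than for men (36.4%–77.1%), so the
intervention narrows the large baseline gap in cycling participation.

The causal chain the model encodes is:

1. **Uptake.** Each gender's baseline weekly cycling prevalence $p_g$
   becomes $p_g' = \min\{p_g (1 + u_g),\, 1\}$ under a scenario with
   relative increase $u_g$.
2. **Activity redistribution.** New cycling means more weekly physical
   activity: a share of each of the three non-top activity levels
   (*inactive*, *low*, *some*) is promoted exactly one level; people
   already meeting the aerobic guidelines stay put.
3. **Costing.** Population lifetime costs are head counts times
   per-person lifetime costs, in £ billions:
   $C_{g\ell} = N_{g\ell}\, c_{g\ell} / 10^6$ with $N$ in persons and $c$
   in £ thousands. The *dementia-related* scope sums dementia health
   care, dementia social care and unpaid-carer costs; the *total* scope
   adds health and social care for other diseases.

Because preventing dementia extends life, and longer life accrues
other-disease costs, total savings are systematically smaller than
dementia-related savings; the model reproduces that ordering by
construction of the cost table, and the test suite asserts it.

## Inputs

Four published tables ship as plain-text fixtures under `inst/extdata/`,
transcribed exactly as printed (including their rounding inconsistencies;
validators use tolerances, never silent repair):

* `activity_levels_hse2021.csv` — activity-level percentages by gender
  and age band from the Health Survey for England 2021. Printed columns
  sum to 99–101%, so the row-sum validator accepts deviations up to
  ±0.02.
* `lifetime_costs_per_person.csv` — per-person lifetime costs by gender,
  activity level and category (£ thousands, 2024 prices), derived from
  the published dynamic Markov model of Van Baal and colleagues and the
  unpaid-care estimates of Livingston and colleagues.
* `cycling_patterns.csv` / `uptake_increases.csv` — weekly cycling
  prevalence by gender with scenario projections and gender-gap rows,
  and the two scenarios' relative uptake increases.
* `dementia_relative_risks.csv` — dementia incidence multipliers per
  activity level relative to the inactive reference (low 0.65, some
  0.65, meets 0.62).

Two baseline cycling figures exist in the sources: weekly cycling
(2.79% women, 8.89% men) and cycling 2–5 km (2.6% / 8.7%). The weekly
figures are canonical here — the scenario table is built from them — and
the 2–5 km set is available behind the `baseline_source` config switch.

The population counts behind the published £-billion tables are census
figures that are not themselves printed. The package therefore offers
three population sources: back-calibration (default), a user-supplied
census-style file, or the synthetic generator.

## The mover rule: a deliberately explicit design choice

The sources state *that* a proportion of each non-top level moves up one
level, but never quantify it, and the published scenario columns do not
pin down a single rule (the implied per-level mover fractions are
mutually inconsistent between genders). The package therefore treats the
published scenario columns as non-binding diagnostics and adopts one
transparent rule:

> the promoted mass per gender equals the percentage-point increase in
> cycling prevalence — the new cyclists are the people who move up one
> activity level — applied identically across age bands.

Two split policies decide *which* people move:

* `proportional` (default): total mover mass $\delta_g$ is split across
  the three movable levels in proportion to their current shares.
* `uniform_fraction`: every movable level promotes the same fraction
  $\delta_g / (1 - s_{\text{meets}})$ of itself.

For a distribution whose shares sum to exactly 1 the two coincide; they
differ only on as-printed (rounded) rows. Mover demand exceeding the
movable mass is capped — everyone movable is promoted once — with a
warning, never a negative share. Mass is conserved exactly and no mass
moves more than one level per application; both are asserted as
properties over randomized simplex inputs.

## Back-calibration

With per-person costs $c_{g\ell} > 0$ and published population costs
$T_{g\ell}$, the implied counts are
$N_{g\ell} = T_{g\ell} \times 10^6 / c_{g\ell}$, and re-aggregation
reproduces $T$ to machine precision. Back-solving the baseline column
gives ≈ 46.5 million people aged 16–64 across levels — larger than
England-only census figures, suggesting UK-wide counts or an unstated
scaling in the source. The package flags this but does not resolve it:
calibration is a round-trip identity, not a claim about the true census.

The split of "dementia-related" costs is itself a derived choice: the
sources never list the categories, but only
dementia health care + dementia social care + unpaid care matches the
published per-person to population-level ratio (0.3903 vs 0.3909 for
inactive women). The test suite asserts this derivation.

## The three-state cohort engine

`propagate()` runs the structure underlying the cost inputs: an
annual-cycle Markov cohort over *no dementia*, *dementia* and *death*,
stratified by gender, age and activity level. Within a cycle, death is
evaluated per state and dementia onset applies to the no-dementia
survivors with probability $i(a)\,\mathrm{RR}_\ell$; death is absorbing
and there is no remission. The source calibration (English incidence and
mortality schedules) is not published, so the engine takes rates as
inputs and the synthetic module supplies Gompertz-shaped defaults.

Numerical choices, all overridable:

* **Discounting** defaults to 0 (the sources are silent); any annual
  rate can be passed (3.5% is the UK-conventional option).
* **No half-cycle correction** by default; end-of-cycle occupancy counts
  as that cycle's person-years.
* **Age grid**: annual cycles from 16 (the cohort interpretation of the
  16–64 scope) to 100.
* Other-disease costs accrue per person-year alive in either alive
  state; dementia-specific care and unpaid care accrue per person-year
  with dementia.

Correctness is checked against an independent transition-matrix-power
oracle (exact on short instances), closed-form geometric sums for
constant-rate cohorts, and monotonicity of dementia years and costs in
the relative risk.

## Probabilistic sensitivity analysis

`run_psa()` follows standard practice for decision models: Beta
distributions for probabilities, Gamma for costs, fitted by method of
moments from a mean and 95% CI with $\sigma = (\text{high} -
\text{low}) / (2 \times 1.96)$. Costs take ±20% CIs around the base
case; the same ±20% default is applied to probabilities (the sources
state the rule only for costs — this extension is a package default, and
any spec row can be edited or frozen). Summaries are means with
2.5/97.5 percentile intervals over 1000 draws by default.

Design choices worth knowing:

* Parameters are sampled **independently**; no correlation structure is
  imposed (a documented limitation).
* Activity-share vectors are sampled per component and renormalised onto
  the simplex; the number of renormalised draws is reported.
* One global integer seed governs everything through per-parameter
  sub-streams derived from a hash of the parameter id, so adding a
  parameter never shuffles another parameter's draws, and a fixed seed
  gives bit-identical results.
* With every parameter frozen to its mean the PSA reproduces the
  deterministic model to ~1e-9, which the tests assert.

## Synthetic data

The generators make every stage testable without downloads:

* `simulate_population()` — deterministic apportionment of a total
  (default 35 million, 50.3% women: an order-of-magnitude stand-in,
  explicitly non-census) across the five 16–64 bands by
  largest-remainder rounding, conserving the total exactly.
* `simulate_activity_distribution()` — Dirichlet perturbation centred on
  a template; rows sum to exactly 1, so every draw passes the validator.
* `simulate_cost_table()` — multiplicative Gamma noise with per-row
  rejection sampling that preserves the qualitative cost orderings
  (dementia categories maximal at inactive, other-disease categories
  non-decreasing in activity).
* `simulate_transition_rates()` — Gompertz incidence and mortality with
  a constant dementia excess-mortality factor.

What the synthetic data does *not* emulate: correlated behaviour between
age bands, secular trends, socio-economic structure, or any real census
margin. Passing tests on synthetic inputs demonstrate the arithmetic and
the stated invariants, not real-world calibration.

## Worked example

```{r example, eval = FALSE}
costs <- read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
published <- read_published_population_costs(
  cycledem_example("published_population_costs.csv"))
counts <- calibrated_baseline_counts(published, costs)

res <- evaluate_scenarios(counts, costs, c(women = 0.0279, men = 0.0889))
filter(res$savings$scenario1, gender == "total")

psa <- run_psa(counts, costs, c(women = 0.0279, men = 0.0889),
               n_draws = 1000, seed = 1)
psa$summary
```

The full pipeline — inputs, scenarios, costing, PSA, report files and a
log with input digests — runs from one configuration:

```{r pipeline, eval = FALSE}
run_pipeline(list(psa = list(n_draws = 1000, seed = 1)),
             out_dir = "outputs")
```

## Problem sizes and known limitations

The test suite exercises the randomized properties at 1000 simplex rows
per policy, 25 + 20 short Markov instances against the matrix-power
oracle, 84-cycle lifetime cohorts, and PSA runs of up to 4000 draws; the
acceptance script runs the full 1000-draw PSA. These sizes were chosen
so the whole suite completes in a couple of minutes while keeping
Monte-Carlo checks well-powered.

Limitations inherited from the modelling approach: the uniform stepwise
activity response is a simplification of behaviour change; uptake is
age-uniform within gender; intervention (construction/maintenance) costs
are out of scope, so no cost-effectiveness ratio is computed;
quality-of-life outcomes are not modelled; and the published scenario
tables cannot be reproduced cell-by-cell because their mover rule and
census counts are unpublished — the package reproduces their signs,
orderings and baseline columns instead, and says so rather than
overfitting a rule to printed output.
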
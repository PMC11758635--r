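---
title: "Assessing marine-ranching food webs: mass balance, network indices, grading, capacity and scenario dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing marine-ranching food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranchena)
```

## The problem

Marine ranching — habitat construction (artificial reefs), hatchery release
and managed harvest in a delimited coastal area — needs quantitative answers
to three questions: is the ranched ecosystem in better shape than comparable
unranched water, which species can be enhanced and by how much, and what
happens to the food web if they are. `ranchena` provides a tested pipeline
for all three, built around a static mass-balance food-web model of the
Ecopath type and the ecological network analysis (ENA) indices computed from
it.

## The mass-balance model

A model is a set of functional groups (consumers, one or more primary
producers, exactly one detritus pool) with biomass $B_i$ (wet weight,
t/km²), production ratio $P/B_i$ (/a), consumption ratio $Q/B_i$ (/a),
unassimilated fraction $U_i$, catches and exports (t/km²/a), plus a
prey-by-predator diet matrix $DC_{ij}$ whose consumer columns sum to 1.

With biomasses known everywhere — the configuration used throughout this
package — the master equation is solved directly for each group's
ecotrophic efficiency, the fraction of production consumed, caught or
exported:

$$EE_i = \frac{Y_i + E_i + BA_i + \sum_j B_j (Q/B)_j DC_{ij}}{B_i (P/B)_i}.$$

A model is *feasible* when every $EE_i \le 1$: no group is asked to supply
more than it produces. Respiration closes each consumer's budget,
$R_i = (1-U_i) Q_i - P_i$, unconsumed production and egestion flow to
detritus, and the detritus pool's own $EE$ is its consumed share of total
detrital inflow (the surplus leaves as detrital export). Trophic levels are
1 for producers and detritus and $1 + \sum_j DC_{ji} TL_j$ for consumers,
solved as a linear system so feeding loops are handled exactly; diet imports
contribute at TL 1 by default (configurable), a choice we had to make
because the convention is rarely stated.

A deliberately narrow scope: mixed unknowns (estimating $B$ from an assumed
$EE$), multi-stanza groups and automatic rebalancing heuristics are out of
scope. `diagnose()` reports the usual balancing guidance — gross efficiency
$P/Q$ outside 0.1–0.3, $R/A \ge 1$, $P/R \ge 1$, negative respiration — as
warnings only; feasibility is judged on $EE$ alone, which is how these
checks are used in practice during manual balancing.

## Network indices

`compute_index_set()` returns the ten indicators used for status grading.

* **Lindeman spine.** Every group's consumption is apportioned over integer
  trophic levels by its fractional trophic composition (a forward recursion
  on the diet matrix, truncated when the residual mass is below 1e-10 and
  renormalised). Transfer efficiency at a level is (flow passed up +
  exports) / throughput; the mean TE over levels II–V is the geometric mean
  of the steps (the convention of the major Ecopath implementations;
  arithmetic averaging is a flag). A step with nothing passed on gives a
  mean of zero rather than an undefined logarithm.
* **D/H** is consumption drawn from detritus over consumption drawn from
  producers.
* **FCI** (Finn's cycling index) uses the Leontief inverse of the
  fractional-outflow matrix over living groups plus detritus: the diagonal
  $n_{jj}$ is the mean number of visits a unit of throughflow makes to
  compartment $j$, and the cycled fraction is $(n_{jj}-1)/n_{jj}$. FCI is
  cycled throughflow as a percentage of total system throughput (TST, the
  sum of consumption, exports, respiration and detrital flows). **FML** is
  TST / (exports + respiration).
* **A/C** (relative ascendancy) is computed on the extended flow matrix
  (compartments plus an import row and export/respiration columns), log
  base 2; the ratio is base-invariant.
* **CI** counts realised feeding links among living groups plus links from
  detritus over $N(N-1)$ living-group pairs — the count is stated here
  because published definitions differ. **SOI** weights each consumer's
  prey-TL variance by the natural log of its consumption, excluding
  consumers with $Q \le 1$ t/km²/a (whose log-weights would be non-positive
  or unstable).
* The maturity ratios TPP/TR, TPP/TB and TB/TST come straight from the
  attribute summary.

`biomass_by_integer_tl()` bins living biomass by the nearest integer level
(half-up); an optional `max_level` pools everything above a chosen top
class, the convention used when published trophic pyramids stop at their
highest occupied level.

## Status grading

Grading compares an ecosystem's indicator vector against quintile scales
built from a reference compilation of coastal ecosystems
(`build_grade_scale()`): the 20/40/60/80/100th percentiles of each
indicator's reference distribution become the interval points of the grades
*poor* → *good*, reversed for indicators where larger is worse. The
packaged default scale transcribes the published interval points. Axis
direction is inferred from the ordering of the points rather than from the
published positive/negative labels: one published row (TB/TST) is labelled
negative while its points increase toward *good*, and only the point
ordering reproduces the published membership table. Relative ascendancy is
treated as a plain positive indicator with clamping; folding around the
theoretical optimum near 0.46 would need a rule no source states, and none
of the graded systems exceeds it.

Membership is triangular: a value between adjacent interval points splits
linearly between the two bracketing grades, values beyond the extremes take
full membership in the extreme grade, and every membership vector sums to 1.
The weighted sum of membership rows (weights fixed to the published scheme,
summing to ≈1) gives the aggregate grade vector; the final label is the
maximum-membership grade, with ties broken toward the better grade under a
warning.

```{r grading}
scale <- load_fixture("grade_scale")
weights <- load_fixture("weights")
idx <- load_fixture("ena_indices")
membership(idx$ranch[["CI"]], "CI", scale)
evaluate_status(idx$ranch, scale, weights)$grade
```

## Carrying capacity and enhancement potential

The ecological carrying capacity of a group is the largest biomass it can
hold while the whole model stays feasible, all other inputs fixed. The
search expands the biomass geometrically (factor 2) until balance fails,
then bisects to a relative tolerance of 1e-4; if nothing binds below 10⁶
times the baseline the capacity is reported as unbounded rather than as a
number. Capacity binds only through prey depletion (the target's own $EE$
falls as its biomass rises, and its predators' biomasses are fixed), and
"unbalanced" is strictly any $EE > 1$ — the diagnostics warnings do not
bound capacity, because they do not bound it during manual balancing
either. Enhancement potential is capacity minus current biomass, ranked
within trophic-level bins 2.0–2.5, 2.5–3.0 and 3.0–3.5 (lower bound
inclusive). `merge_groups()` builds aggregate enhancement groups (e.g. a
mussels–oysters–barnacles complex) with biomass-weighted rates and
consumption-weighted diets, conserving every flow.

## Scenario dynamics

`simulate_scenario()` integrates foraging-arena dynamics calibrated to the
balanced model. Each realised link gets an arena flow
$Q_{ij}(B_i, B_j) = \dfrac{v_{ij} a_{ij} B_i B_j}{v_{ij} + a_{ij} B_j}$
whose two parameters are fixed by (i) reproducing the mass-balance flow
exactly at baseline biomasses and (ii) letting predation mortality saturate
at $v^{new}_j$ times its baseline value as predator biomass grows — the
standard vulnerability-multiplier contract. Vulnerabilities come from the
trophic level via $v_i = 0.1515\,TL_i + 0.0485$ and
$\log v^{new} = 2.301958\,v_i + 0.001051$ (natural log, so the
mixed-control value $v = 0.3$ maps to a multiplier of about 2). Growth
efficiency is baseline $P/Q$; other mortality is baseline $P/B\,(1-EE)$;
producers follow a saturating production response with maximum $P/B$ twice
baseline; the detritus pool is a state variable receiving egestion and
other-mortality flows; fishing applies the baseline $F = $ catch$/B$ as a
constant rate when switched on. With nothing perturbed the system is
stationary by construction — the core consistency property, tested to
machine precision.

Enhanced groups are biomass-forced: a linear ramp to target over the first
year (the ramp length is a parameter; no source states one), then held.
Mediation effects — a mediator group's biomass rescaling the vulnerability
of chosen links through a sigmoid normalised to 1 at baseline — default to
a sheltering shape (floor 0.5, ceiling 2, negative steepness) and are fully
configurable, since the published mediation settings are not printed.
Collapse is biomass below 10⁻³ of baseline; a run with any collapsed living
group is "not evaluable", mirroring how such scenarios are reported.

Numerics: the reported grid is monthly and the integrator is fixed-step
RK4, but explicit RK4 at a bare monthly step diverges when turnover is fast
(plankton $Q/B$ near 190/a means rate × step ≈ 16). The integrator
therefore sub-steps internally so that the fastest baseline turnover rate
times the step stays at or below 0.2; `substeps` overrides the automatic
choice, and halving the step moves 14-year endpoints by well under 0.1%.

`snapshot_and_evaluate()` rebuilds a model at the snapshot year — simulated
biomasses, diet columns from the realised arena flows, baseline rates
retained — solves it and grades it. `run_scenario_suite()` enumerates every
combination of the enhancement groups with and without fishing plus a
fishing-only run; with three groups that is the full 15-scenario design.

## Synthetic webs and what passing tests show

`generate_model()` draws layered trophic-pyramid webs: producers at
15–40 t/km² with $P/B$ 80–150/a, consumer layers whose biomass is a few
percent of the layer below, $Q/B$ decaying by layer from 80/a, gross
efficiencies uniform in 0.1–0.3, unassimilated fractions 0.2–0.4, and
Dirichlet-style diets over strictly lower layers plus 10–40% detritus.
Candidates failing the $EE \le 1$ criterion are rejected and redrawn
(budget 1000 attempts); generation is deterministic per seed and restores
the caller's RNG state. These webs exercise every algorithm end to end, but
they are acyclic apart from detrital loops, have no imports, seasonality,
multi-stanza structure or survey noise — so green tests demonstrate
algorithmic correctness, not fidelity to any particular real ecosystem.

The packaged fixtures transcribe the published study tables (group
parameters for a 23-group ranched and 19-group control ecosystem, the grade
scale, weights, attribute totals, indicator values and capacities). The
study's full diet matrices were published only as appendix material and are
not packaged; the ecosystem fixtures therefore carry `diet = NULL` with a
placeholder flag, and full-model re-solution is validated on synthetic webs
instead.

Problem sizes used by the test suite — webs of 5–8 groups, 20-seed capacity
cross-checks, 100-seed pipeline closure, 14-year simulations on three-group
systems — were chosen as the smallest sizes that still exercise every code
path and oracle comparison.

## Known limitations

* Only the all-$B$-known solving configuration is supported.
* The arena model is the canonical foraging-arena form; published scenario
  trajectories from a particular Ecosim build are not expected to be
  reproduced value-for-value (engine internals such as mediation settings
  and forcing protocol are not printed), and are treated as directional
  checks only.
* Quintile scales need at least five non-degenerate reference values per
  indicator; constant references are an error, not a silent scale.
* The capacity search assumes the baseline is feasible and perturbs one
  group at a time; a combined-group capacity is whatever the merged model
  yields, and no claim is made about matching any published combined value.
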
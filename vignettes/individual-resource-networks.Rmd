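---
title: "Individual-resource networks: metrics, null models, and synthetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-resource networks: metrics, null models, and synthetic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indivnet)
```

## The problem

Generalist populations are often collections of relatively specialized
individuals. Representing a population as a bipartite network — individual
consumers on one side, food-item categories on the other, a link wherever an
individual's sample contained an item — makes that internal structure
measurable. Two patterns matter most:

* **Nestedness**: specialists eat subsets of what generalists eat. We
  quantify it by *matrix temperature* T, the departure of the optimally
  packed incidence matrix from perfect nestedness (T = 0 is perfectly
  nested, T = 100 maximally "hot"), and report the rescaled
  N = (100 − T)/100 alongside T.
* **Modularity**: distinct groups of individuals specialize on distinct
  resource sets. We quantify it with Newman–Girvan Q maximized by greedy
  agglomeration on the bipartite graph treated as unipartite.

Because both metrics have strong size and fill dependence, observed values
are calibrated against Erdős–Rényi null ensembles via Monte Carlo p-values
and standardized effect sizes (SES), and then related to environmental
predictors (food-resource availability, habitat structure) by simple linear
regressions across site-by-season populations.

## From records to matrices

Input is long-format diet-occurrence data: one row per
(individual, site, season, capture date, item). Two rules shape the
matrices:

* **One sample per individual per season.** Repeated captures of the same
  individual within a season are statistically dependent, so
  `dedupe_one_per_season()` keeps a single capture event per
  (individual, site, season): the earliest dated event by default, with
  undated events falling back to input order. The source data never state
  which of several samples was retained, so the rule is explicit and
  switchable (`rule = "union"` pools all events instead).
* **Occurrence, not counts.** A cell is 1 if the item occurred in the
  retained sample at least once. Counting fragments of arthropods or seeds
  overstates precision; occurrence is the conservative choice.

`build_incidence()` then yields a binary matrix per site × season with no
all-zero rows or columns. Sampling completeness of the item inventory is
assessed with Chao1 (`chao1()`), using the classic
`S_obs + f1^2/(2 f2)` estimator, or the bias-corrected additive term
`f1(f1-1)/2` when there are no doubletons.

## Matrix temperature

`matrix_temperature()` implements the temperature of Rodríguez-Gironés &
Santamaría (2006). Cell centers of the packed matrix are mapped onto the
unit square; an isocline of perfect nestedness
`y(x) = 1 − (1 − (1 − x)^p)^{1/p}` — with `p` solved so the area under the
isocline equals the matrix fill — separates the region where presences are
expected from the region where absences are. Each misplaced cell
contributes the square of its normalized distance from the isocline along
the cell's 45° diagonal; the sum is scaled by `U_max = 0.04145` so T lies
in [0, 100]. Numerical choices: the fill parameter is found by root
bracketing on a fixed 2001-point Simpson grid (relative error well below
1e−4), and per-cell isocline crossings by `uniroot` at tolerance 1e−10, so
scoring is deterministic.

Temperature is defined at the *optimal* packing, so the reported T is the
minimum over row/column orderings:

* matrices up to 5 × 5 are scored over **every** ordering (at most
  14,400), so the minimum is exact;
* larger matrices start from a canonical degree-sorted packing (ties broken
  by row/column pattern, which also makes the result invariant to input
  ordering) refined by seeded stochastic swap hill-climbing with restarts.
  `effort = "fast"` uses 4 restarts × 60(I+R) sweeps; `"thorough"` 16 ×
  250(I+R). The search is a design choice: any optimizer is admissible
  because correctness is checked against exhaustive enumeration on small
  matrices, not against a particular search strategy.

One subtlety worth knowing: a matrix whose rows are subset-ordered but
contain *tied* row patterns (flat steps) scores slightly above zero,
because the step boundary cannot coincide with the smooth isocline. This
matches the reference implementation in `vegan::nestedtemp`, against which
the scoring function is cross-checked in the test suite. Only strict
staircases reach T = 0 exactly.

## Modularity

`fast_greedy_modularity()` delegates the agglomeration to igraph's
deterministic fast-greedy implementation on the bipartite graph treated as
unipartite (no one-mode projection), returning the partition of maximal Q
along the merge path. The test suite checks it against an independent
exhaustive-partition oracle on small graphs: greedy Q never exceeds the
true maximum and attains it on cleanly separated two-block matrices.
Because igraph's merge order is deterministic, no additional tie-breaking
configuration is exposed.

## Null models, p-values and SES

The Erdős–Rényi null is implemented in the two readings that circulate for
"random networks of the same size": `bernoulli_half` (every link present
independently with probability 0.5 — the default) and `match_connectance`
(exactly the observed number of links placed uniformly). The pipeline
records which mode produced every p-value. Degenerate draws are handled per
metric: temperature prunes empty rows/columns and requires a 2 × 2 core;
modularity requires at least one edge; draws on which the metric is
undefined are redrawn and the redraw count is logged.

`monte_carlo_test()` uses the two-sided plus-one-corrected p-value
`p = min(1, 2 min(p_low, p_high))` with
`p_high = (#\{sim ≥ obs\} + 1)/(n_sim + 1)`; two-sided because both
significantly low and significantly high metrics are interpretable.
`standardized_effect_size()` is `(obs − mean(null))/sd(null)` with the
sample SD; under an approximately normal null, |SES| > 2 marks
significance. Both properties — type-I error near the nominal 5% level and
roughly 95% of null-generated SES values inside [−2, 2] — are verified by
simulation in the test suite and recomputed from scratch by
`scripts/acceptance.R`.

## Environmental predictors and regressions

Per site × season: exponential Shannon diversity `exp(H′)` of arthropod
order dry masses (a Hill number of order 1: the effective number of
equally abundant orders), total arthropod dry mass, and `log10(count + 1)`
fruit availability (base and offset configurable; the offset keeps zero
counts defined). Habitat structure (8 station-level variables) is
summarized by one PCA over all stations pooled across sites and seasons —
per-season PCAs would put the site × season points on incomparable axes —
with variables Z-scored first and axis signs fixed so the
largest-magnitude loading of each axis is positive. Site × season scores
are station means on PC1/PC2.

`fit_metric_regression()` is ordinary least squares with the two-sided
slope p-value; with a typical design of 8 site × season points power is
low, so `n` travels with every fit. Season-within-site points are not
strictly independent; no mixed model is fitted — the analysis stays at the
level of simple regressions by design. `collinearity_screen()` reports
pairwise Spearman ρ and p among resource predictors (flag at p ≤ 0.1).
Connectance is computed but excluded from regressions by default because
it is strongly negatively coupled to modularity; `regress_connectance`
re-enables it.

## The synthetic-data generator

The three classic individual diet-specialization models are verbal
hypotheses; this package gives them one explicit parameterization so the
pipeline can be exercised end to end without field data:

* **Shared preference** (`simulate_shared_preference`): one global resource
  ranking; individual niche breadths drawn uniformly from
  `breadth_distribution`; diets are prefixes of the ranking, hence
  perfectly nested by construction.
* **Distinct preference** (`simulate_distinct_preference`): each individual
  has its own ranking; realized breadth
  `round(b_min + density (b_max − b_min))` grows with forager density as
  competition forces diet expansion, so specialization is strongest at low
  density.
* **Competitive refuge** (`simulate_competitive_refuge`): all individuals
  share a `core_size` top-ranked set; the remaining resources are split
  into `n_groups` disjoint alternative groups, each individual draws a
  fraction `density` of its assigned group, so modular structure grows
  with density.

All three finish with symmetric bit-flip noise and pruning of empty
rows/columns. `density` is an abstract [0, 1] control, not an estimated
animal density. Defaults emulate the motivating study design: 4 sites ×
2 seasons, 27–72 individuals per cell, 20 food items; the default study
ties density to season (0.3 cool-dry, 0.9 warm-wet) so the warm-wet
season is the population-dense, resource-rich one.

`simulate_environment()` produces matched covariates: log-normal arthropod
order masses whose spread shrinks (evenness rises) in the warm-wet season,
negative-binomial fruit counts with a warm-wet multiplier, and habitat
stations generated from a fixed 2-factor loading structure (a
vegetation-density factor and a tree-structure factor) plus independent
noise, with a seasonal shift on the vegetation factor. Every generator is
bit-reproducible from its manifest (`simulate_study(manifest = ...)`).

What the generator does *not* emulate: detection error in fecal analysis,
spatial autocorrelation among stations, temporal trends within a season,
and any real taxonomic composition. Passing tests demonstrate that the
pipeline recovers constructed signal of realistic size and calibrates its
nulls correctly — not that any particular field system behaves like the
models.

## Problem sizes and runtime defaults

Simulation-based checks in the test suite are scaled to run comfortably on
a single CPU: null-calibration uses 150 observed 30 × 20 networks with 200
replicates each; the acceptance script uses 200 × 500 (type-I error) and
300 × 500 (SES coverage); exhaustive temperature verification samples 500
random 4 × 4 matrices; sign tests over generator seeds use 50 seeds. The
temperature search cost is O(L) per swap; a fast-effort optimization of a
30 × 20 matrix takes well under a second, so nestedness null ensembles of
1,000 draws are minutes-scale — choose `n_sim` accordingly in
`run_study()` configs.

## Known limitations

* The temperature optimizer is exact only up to 5 × 5; beyond that the
  reported T is the best packing found (an upper bound on the true
  minimum). The thorough preset tightens but does not guarantee it.
* The ER nulls are not degree-preserving; fixed-margin nulls are out of
  scope.
* Regression inference across site × season points inherits the usual
  caveats of n = 8 designs and seasonal pseudo-replication.
* Chao1 coverage treats item categories as exchangeable species; coarse,
  heterogeneous categories (e.g. "fruit fiber morphotypes") stretch that
  assumption.
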
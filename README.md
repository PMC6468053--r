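# indivnet

Individual-resource network analysis for diet-occurrence data.

Generalist populations are often collections of relatively specialized
individuals. `indivnet` is for ecologists who sample individual diets
(e.g. fecal samples from trapped small mammals) across sites and seasons
and want to know how the *within-population* interaction structure —
nestedness and modularity of the individual × food-item network — varies
with food-resource availability and habitat structure.

## What it computes

For each site × season population the package builds a binary incidence
matrix (rows = individuals, one retained sample per individual per season;
columns = food-item categories; cell = occurrence) and computes:

* **Connectance** `C = L / (I · R)` — realized fraction of possible links.
* **Degree distribution** — proportion of individuals using *n* items.
* **Chao1 coverage** — `S_obs / S_est` with
  `S_est = S_obs + f1²/(2 f2)` (singletons `f1`, doubletons `f2`;
  bias-corrected additive term when `f2 = 0`).
* **Nestedness** via matrix temperature `T ∈ [0, 100]`
  (Rodríguez-Gironés & Santamaría's unexpectedness scoring, minimized over
  row/column packings: exact enumeration up to 5 × 5, seeded hill-climbing
  with restarts beyond), reported with `N = (100 − T)/100`.
* **Modularity** — Newman–Girvan `Q` maximized by fast-greedy agglomeration
  on the bipartite graph treated as unipartite (igraph).
* **Null calibration** — Erdős–Rényi ensembles (independent 50% links, or
  connectance-matched), two-sided plus-one Monte Carlo p-values, and
  standardized effect sizes `SES = (obs − mean(null)) / sd(null)`, with
  |SES| > 2 read as significant under the normal approximation.
* **Environmental regressions** — exp(H′) arthropod diversity (Hill number
  of order 1 on order-level dry mass), total arthropod mass,
  log10(fruit count + 1), and habitat PC1/PC2 (one pooled, Z-scored PCA of
  8 structural variables), each regressed on nestedness and modularity by
  OLS across site × season points.

A synthetic-study generator implements the three classic individual
diet-specialization models — shared preference, distinct preference,
competitive refuge — plus matched seasonal environmental covariates, so
the entire chain is testable without field data. See the methods vignette
(`vignettes/individual-resource-networks.Rmd`) for the models, parameter
meanings and numerical choices.

## Worked example

A fully synthetic 4-site × 2-season study under the competitive-refuge
model, with forager density tied to season (0.3 cool-dry, 0.9 warm-wet):

```r
library(indivnet)
report <- run_study(list(
  simulate = list(seed = 11L),
  null     = list(mode = "bernoulli_half", n_sim = 199L, seed = 11L),
  metrics  = list(effort = "fast")))
report$rows[, c("site", "season", "n_individuals", "connectance",
                "temperature", "modularity", "modularity_ses")]
#>   site   season n_individuals connectance temperature modularity modularity_ses
#> 1   S1 cool_dry            68       0.353        39.9      0.190           9.13
#> 2   S1 warm_wet            55       0.454        47.2      0.282          18.61
#> 3   S2 cool_dry            34       0.351        37.7      0.182           3.96
#> 4   S2 warm_wet            62       0.452        49.2      0.289          22.66
#> 5   S3 cool_dry            46       0.352        40.5      0.182           5.27
#> 6   S3 warm_wet            34       0.451        46.6      0.289          14.18
#> 7   S4 cool_dry            50       0.358        37.0      0.177           5.12
#> 8   S4 warm_wet            65       0.449        48.1      0.287          22.40
```

Every warm-wet population (the dense, resource-rich season in the
generator) has markedly higher modularity and modularity SES than its
cool-dry counterpart — the signature of the competitive-refuge mechanism,
where crowding pushes individuals onto their distinct alternative-resource
groups. The regression table picks up the matching environmental signal;
at `seed = 11` the significant fits (p < 0.05, n = 8) are:

```r
report$regressions[report$regressions$significant,
                   c("predictor", "response", "slope", "r_squared", "p_value")]
#>              predictor   response   slope r_squared p_value
#> 1  arthropod_diversity nestedness -0.0264     0.569 0.03067
#> 3            log_fruit nestedness -0.1021     0.804 0.00254
#> 8            log_fruit modularity  0.1048     0.680 0.01175
#> 10           pc2_score modularity -0.0587     0.517 0.04452
```

i.e. modularity rises with fruit availability across these synthetic
populations, as constructed. Single matrices can be analyzed directly:

```r
m   <- simulate_diet_model(diet_model_params("competitive_refuge",
         n_individuals = 30, density = 0.8, seed = 7))
met <- network_metrics(m, seed = 1)
monte_carlo_test(met$modularity, function(x) fast_greedy_modularity(x)$modularity,
                 m, n_sim = 999, seed = 1, metric_name = "modularity")
```

A thin command-line front end over the same functions ships at
`inst/cli/indivnet.R` (subcommands `build`, `metrics`, `nulltest`,
`simulate`, `run`).

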
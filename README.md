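# pbcnet

Quantitative tests of faunal provincialism in the fossil record. The
motivating system is the Late Cretaceous Western Interior of North
America, where ceratopsid and hadrosaurid dinosaurs have long been argued
to form distinct northern and southern Laramidian provinces — and where
that apparent endemism may instead be a sampling artifact. The package is
for palaeobiologists who want to run that style of analysis on their own
occurrence data and phylogenies, end to end, with the resampling and
bias diagnostics built in.

## What it computes

**Biogeographic Connectedness** on a taxon x region network:

    BC = (O - N) / (L*N - N)

with `N` taxa, `L` regions, and `O` occupancy links — 0 means complete
endemism, 1 complete cosmopolitanism. The **phylogenetically corrected**
form (pBC) lets a taxon partially occupy a region it is absent from,
with weight `exp(-d/mu)`, where `d` is the patristic distance (Myr, on a
time-calibrated ultrametric tree) to the region's phylogenetically
nearest occupant and `mu` is a decay constant (default 10 Myr; pBC
collapses to BC as `mu -> 0` and saturates at 1 as `mu -> infinity`).

Around the statistic the package provides:

* minimum-branch-length time-scaling of fossil trees from FAD/LAD tables,
  ultrametricization, pruning, patristic distances (`timescale_mbl()`,
  `make_ultrametric()`, `prune_tree()`, `patristic_matrix()`);
* delete-d jackknife, rarefaction curves with 95% CIs, a
  region-relabelling permutation null, and a latitudinal subsampling
  experiment that imposes a two-peak "Campanian-style" sampling window
  (`jackknife_pbc()`, `rarefy_pbc()`, `permutation_null()`,
  `subsample_experiment()`, `compare_distributions()`);
* sampling-bias diagnostics: 1-degree latitudinal binning, Spearman/
  Kendall correlation of occurrence vs collection curves, and
  maximum-likelihood GLS with AR(1) errors plus AICc/Akaike-weight model
  selection over outcrop/exposure covariates (`bin_by_latitude()`,
  `correlate_series()`, `fit_gls_ar1()`, `model_selection()`);
* seed-deterministic synthetic-data generators with known ground truth
  (`scenario_config()`, `simulate_tree()`, `assign_regions()`,
  `simulate_sampling()`, `simulate_covariates()`), plus a config-driven
  orchestrator (`run_analysis()`) and PBDB-flavoured CSV readers.

Everything tabular goes in and out as tibbles; results support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

A synthetic Campanian-style fauna: two wholly endemic clades, collections
concentrated at the 36-37°N and 49-51°N sampling peaks.

```r
library(pbcnet)

cfg <- scenario_campanian(n_taxa = 20, region_scenario = "endemic_clades", seed = 42)
sim <- simulate_scenario(cfg)

taxa <- intersect(unique(sim$occurrences$taxon), sim$tree$tip.label)
tree <- prune_tree(sim$tree, taxa) |>
  timescale_mbl(sim$ages, mbl = 1) |>
  make_ultrametric()

inc <- build_incidence(sim$occurrences, time_bin = "Campanian")
compute_pbc(inc, patristic_matrix(tree), mu = 10)
#> # A tibble: 1 × 6
#>   statistic  value     O     N     L    mu
#>   <chr>      <dbl> <dbl> <int> <int> <dbl>
#> 1 pBC       0.0369  39.4    38     2    10

permutation_null(sim$occurrences, tree, time_bin = "Campanian",
                 mu = 10, reps = 999, seed = 1)
#> <pbc_permutation> observed pBC 0.03694 vs 999 permutations: p = 0 (less)

glance(jackknife_pbc(sim$occurrences, tree, time_bin = "Campanian",
                     mu = 10, reps = 1000, seed = 2))
#> # A tibble: 1 × 9
#>   label               observed n_reps   mean       sd   q2.5 median  q97.5  seed
#>   <chr>                  <dbl>  <int>  <dbl>    <dbl>  <dbl>  <dbl>  <dbl> <dbl>
#> 1 jackknife (retain …   0.0369   1000 0.0369 5.44e-17 0.0369 0.0369 0.0369     2

correlate_series(
  bin_by_latitude(sim$occurrences, extent = c(25, 60))$count,
  bin_by_latitude(sim$collections, extent = c(25, 60))$count
)
#> # A tibble: 1 × 5
#>     rho    p_rho   tau    p_tau     n
#>   <dbl>    <dbl> <dbl>    <dbl> <int>
#> 1 0.988 2.44e-28 0.922 3.43e-10     35
```

Reading the output: pBC near zero with permutation p = 0 says the fauna
is far more endemic than a random relabelling of regions — the two-clade
scenario is built to produce exactly that. The jackknife distribution is
degenerate here because with two perfectly symmetric endemic clades every
cross-region distance passes through the root, so every subsample gives
the same value; real (asymmetric) data yield a proper spread. The near-1
rank correlations flag that occurrences track collecting effort across
latitude — the signature of the sampling bias the subsampling experiment
and the GLS model selection then interrogate.

The full chain (time-scaling through model selection) can also be run
from one configuration:

```r
report <- run_analysis(list(
  scenario = list(n_taxa = 30),
  reps = 1000,
  subsample = list(enabled = TRUE, lat_band = c(35, 50), removal = 0.95,
                   thresholds = c(0.08, 0.8)),
  seed = 1
))
write_report(report, "results/run1")
```

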
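# streambeta

Incidence-based beta-diversity analysis for communities sampled along
elevational stream gradients: who replaces whom between sites, how much of
the compositional change is species *turnover* versus *nestedness* (poorer
sites being subsets of richer ones), and how far geography, elevation and
microhabitat each go in explaining it. The package is written for community
ecologists working with site-by-species presence/absence tables from a set
of surveyed transects — the typical product of amphibian larvae,
macroinvertebrate or fish surveys in montane streams.

## What it computes

For every site pair with shared species count *a* and exclusive counts
*b*, *c*, the Sørensen total dissimilarity is partitioned after Baselga:

    beta_sor = (b + c) / (2a + b + c)                  total
    beta_sim = min(b, c) / (a + min(b, c))             turnover
    beta_sne = beta_sor - beta_sim                     nestedness-resultant
             = |b - c| / (2a + b + c) * a / (a + min(b, c))

with the additive identity enforced to 1e-12 on every pair. The per-pair
ratio beta_sne / beta_sor, averaged, classifies the dominant component
(< 0.5 turnover, > 0.5 nestedness).

Around the partition sits the full inferential chain:

* survey merging (species union across years) and explicit exclusion of
  empty transects;
* Shapiro normality reporting and Spearman collinearity screening of the
  environmental variables (dropping, e.g., water temperature when it
  tracks elevation at |rho| >= 0.7);
* haversine geographic, elevational and standardized-Euclidean
  environmental distance matrices;
* Mantel permutation tests (site-relabelling null, 9999 permutations,
  exact enumeration available for <= 7 sites) between every beta component
  and every explanatory distance;
* descriptive distance-decay OLS fits for plotting;
* multiple regression on distance matrices (MRM) with permutation
  inference on R² and coefficients;
* exact hierarchical partitioning of the MRM R² into per-predictor
  independent contributions via all-subset fits and Shapley weights
  (supports the full 13-predictor design: geography, elevation and eleven
  microhabitat distances).

Because field occurrence data of this kind are rarely public, the package
includes a seeded scenario generator (`generate_scenario()`) that plants
known turnover/nested/mixed/neutral structure along an elevational
gradient — including empty transects and a temperature column
rank-correlated with elevation — so the whole chain is testable end to end.

## Worked example

```r
library(streambeta)

cfg <- read_scenario_config(
  system.file("extdata", "montane_scenario.yaml", package = "streambeta"))
report <- run_full_analysis(scenario = cfg, n_perm = 9999, seed = cfg$seed)
report
```

```
Beta-diversity analysis report
  sites retained: 15 of 18
  excluded (empty): site_11, site_13, site_15
  variables removed by screening: water_temp, total_p, conductivity, total_n
Pairwise beta-diversity summary (105 pairs)
  total (Sorensen)     : 0.258 +/- 0.119
  turnover (Simpson)   : 0.192 +/- 0.122
  nestedness-resultant : 0.066 +/- 0.055
  beta-ratio           : 0.318 +/- 0.309
  dominant component   : turnover
Mantel grid:
  predictor   component        r      p
1 geography   total       0.615  0.0001
2 geography   turnover    0.627  0.0001
3 geography   nestedness -0.0634 0.674
4 elevation   total       0.596  0.0001
5 elevation   turnover    0.619  0.0001
6 elevation   nestedness -0.0883 0.751
7 environment total       0.302  0.0068
8 environment turnover    0.283  0.0108
9 environment nestedness  0.0259 0.433
```

Reading this: three transects held no animals and were excluded before any
pairwise statistic; screening removed water temperature (planted to track
elevation at |rho| ≈ 0.81) plus three chance flags; the mean beta-ratio of
0.32 classifies the assemblage as turnover-dominated; and total
dissimilarity and its turnover component decay significantly with
geographic, elevational and environmental distance while the nestedness
component shows no distance structure — the signature of
environmental-filtering-driven species replacement along the gradient.

Downstream results are tibbles via broom-style verbs:

```r
glance(report$partition)   # MRM R^2 and permutation p per beta component
tidy(report$partition)     # coefficients, p, independent contributions (%)
plot_decay_panels(report)  # nine distance-decay panels, Mantel-flagged
write_report(report, "beta_run")  # CSV bundle + JSON manifest
```

For the same run, `glance(report$partition)` prints R² = 0.48 (p = 0.0011)
for total dissimilarity, 0.51 (p = 0.0001) for turnover and 0.14
(p = 0.75) for nestedness, and the tidy table ranks geographic and
elevational distance as the largest independent contributors to total
dissimilarity in this scenario.

Real data enter through `read_occurrence()`, `read_transect_meta()` and
`read_env_table()` (CSV/TSV, auto-detected delimiter, counts binarized on
read), passed to `run_full_analysis(occurrence =, meta =, env =, ...)`.

## Documentation

The methods vignette (`vignettes/beta-diversity-methods.Rmd`) documents
the models, the permutation conventions, the generator's regimes and
calibration targets, and the package's numerical choices and limitations.
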
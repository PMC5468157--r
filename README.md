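# habvuln

Climate-change vulnerability assessment of species habitat from
presence-background suitability models, on an equal-area raster grid.

`habvuln` is built for the workflow conservation biogeographers use to ask
"how much of this species' habitat survives a climate scenario, and how much
of it is protected?" — the canonical example being the giant panda
(*Ailuropoda melanoleuca*) in the Qinling Mountains, whose montane bamboo
habitat is projected against a mid-century warming scenario and overlaid
with the region's 19 nature reserves. The package implements the whole
chain as tested, seed-reproducible R:

1. **Occurrence preparation** — one presence record per 1-km cell
   (`thin_one_per_cell()`), and target-group background points drawn from
   the forest mask (`sample_background()`, default 10,000), so presences and
   availability share a sampling universe.
2. **Variable screening** — pairwise Pearson correlations at the model
   points with greedy elimination of pairs at |r| > 0.8
   (`eliminate_correlated()`), then a second stage that refits on the
   variables whose permutation importance reaches 1%
   (`refit_top_variables()`).
3. **Maximum-entropy suitability model** (`maxent_fit()`) — the
   distribution q over the background sample maximizing the L1-penalized
   presence log-likelihood

   ```
   J(lambda) = mean_presence[ f(x)' lambda ] - log Z(lambda)
               - sum_j beta_j |lambda_j|,
   Z(lambda) = sum_background exp( f(x)' lambda )
   ```

   with linear, quadratic and hinge features f scaled to [0, 1] from the
   background sample, fitted by deterministic cyclic coordinate descent
   with soft thresholding. Logistic output is the entropy-calibrated
   transform `p = e^H q / (1 + e^H q)`. Evaluation uses rank-sum AUC
   (`eval_auc()`), 15 replicated 75/25 subsamples (`run_replicates()`),
   permutation importance and jackknife training gains.
4. **Habitat mapping** — the mean logistic surface cut at the mean
   maximum-sensitivity-plus-specificity threshold (`threshold_max_sss()`,
   `binarize()`), connected patches labeled (`label_patches()`) and
   filtered by the home-range/dispersal rule: remove patches < 4 km² that
   sit > 0.5 km from the nearest retained patch (`filter_patches()`).
5. **Change classification and indicators** (`classify_change()`,
   `indicators()`): cells are unchanged / vulnerable / new / unsuitable,
   and with A_c, A_f, A_fc the current, future and overlapping suitable
   areas,

   ```
   AC   = (A_f - A_c)  / A_c * 100      # area change
   SH_c = (A_c - A_fc) / A_c * 100      # share of current habitat lost
   SH_f = (A_f - A_fc) / A_f * 100      # share of future habitat gained
   ```

   plus a tie-corrected Mann-Whitney contrast of suitable-cell elevations
   (`elevation_contrast()`).
6. **Reserve gap analysis** (`rasterize_reserves()`, `reserve_report()`) —
   per-reserve suitable areas and AC, and the percentage of habitat inside
   the reserve-network union, per scenario.

A synthetic landscape generator (`make_landscape()`, `true_suitability()`,
`sample_occurrences()`, `make_reserves()`) produces spatially
autocorrelated climate surfaces, a warming scenario, elevation, forest and
reserve fixtures from a known truth, so the full pipeline is testable with
no data downloads. Rasters move as ESRI ASCII grids (`read_asc()` /
`write_asc()`), points as `x,y` CSV, reserves as GeoJSON.

## Worked example

```r
library(habvuln)
report <- run_pipeline(default_config(seed = 1, n_occurrences = 200,
                                      n_background = 5000))
print(report)
#> <pipeline_report>
#>   presences 178 (thinned from 200), background 5000
#>   variables: temp1, prec1
#>   AUC test 0.908 +/- 0.009, mean threshold 0.3686
#>   habitat 2234 -> 2043 km2 (AC -8.55%, SH_c 36.71%, SH_f 30.79%)
#>   mean elevation 1925.7 -> 2108.9 m (z = -26.897, p = 2.35e-159)
#>   protection 32.18% current, 30.45% future
```

Reading: on a 100 × 100 km synthetic landscape with a +1.5 °C scenario, the
model (fitted on 178 thinned presences against 5,000 forest background
points, 15 replicates) discriminates presences from background with test
AUC 0.91; the two-stage screen recovers the generating drivers (the first
temperature and precipitation layers) from ten candidates; warming pushes
the suitable band upslope by ~180 m, 37% of current habitat becomes
vulnerable and 31% of future habitat is newly gained; about a third of
habitat falls inside the synthetic 19-reserve network. `run_pipeline(cfg, out_dir = "out/")` writes all
intermediate grids, the reserve table and a JSON/Markdown report.

The published per-reserve area table for the Qinling reserve network ships
in `inst/extdata/` and can be pushed through the same overlay code path
with `synthetic_reserve_grids()`.

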
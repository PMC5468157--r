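---
title: "Methods: presence-background suitability modelling and habitat vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background suitability modelling and habitat vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habvuln)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic landscape does and does not emulate, and the
known limitations.

## The problem

A presence-only survey (here, signs of a montane specialist such as the
giant panda — feces, dens, bed sites, footprints) records where a species
was found, never where it was absent. The question is threefold: where is
habitat suitable today; where will it be suitable under a mid-century
warming scenario; and how much of each falls inside the protected-area
network. All spatial reasoning happens on one equal-area 1-km grid —
inputs must arrive aligned (the readers refuse to resample silently), and
every area is an exact multiple of the cell area.

## The maximum-entropy model

With presence-only data we contrast presences against a *background*
sample describing what the landscape offers. The model is the probability
distribution q over the background sample that is as close to uniform as
possible (maximum entropy) while matching the presence sample's feature
means — equivalently, the Gibbs distribution
`q(x) = exp(f(x)' lambda) / Z` maximizing the L1-penalized presence
log-likelihood

$$J(\lambda) = \bar f' \lambda - \log Z(\lambda) - \sum_j \beta_j |\lambda_j|.$$

Choices, and why:

* **Features.** Linear, quadratic, and forward/reverse hinge features
  (default 5 knots per direction at background quantiles), all scaled to
  [0, 1] by background min/max, clamped outside. Hinge features subsume
  step features, keep the optimizer small, and are the modern default for
  this model family; product and categorical features are deliberately
  omitted.
* **Regularization.** `beta_j = beta_multiplier * s_j / sqrt(m')` with
  `s_j` the feature's background standard deviation and `m'` the presence
  count: penalties shrink with more presences, and features with more
  spread (more capacity to overfit) pay more. `beta_multiplier` defaults
  to 1.
* **Optimizer.** Deterministic cyclic coordinate descent: each coordinate
  takes a soft-thresholded Newton step, backtracking (step halving) until
  the penalized objective does not decrease, features visited in fixed
  column order; convergence when the relative objective change over a full
  cycle is below `tol` (1e-7; `max_iter` 5000 cycles). No stochastic
  initialization, so fits are bit-reproducible. The tests pin the fit
  against a dense grid search over the weight space on small discrete
  backgrounds and against the closed-form Gibbs solution of a one-feature
  two-state system.
* **Outputs.** Raw output is q normalized over the background sample (it
  sums to 1 there). The logistic output `p = e^H q / (1 + e^H q)` uses the
  fitted distribution's entropy H, so a "typical" presence environment
  (q = e^-H) maps to 0.5; the transform is strictly monotone, so both
  outputs rank cells identically.
* **Degenerate inputs.** A constant variable yields a single flagged
  constant feature (its gradient is identically zero, so it cannot
  destabilize the fit); zero-variance features are skipped by the
  optimizer; `NA` anywhere in a cell's inputs makes every derived layer
  `NA` there.

## Evaluation and thresholding

AUC is computed in its rank-sum form (the probability a random presence
outscores a random background point, ties half-credited). Replication is
by independent random 75/25 presence subsamples (default 15 replicates,
background shared); the reported surface is the cellwise mean logistic
grid and the reported threshold the arithmetic mean of per-replicate
thresholds. The threshold maximizes training sensitivity plus specificity
over all distinct observed scores; ties break toward the smallest
candidate, which retains more habitat — a conservative choice for a
conservation application. Thresholds come from training scores only, and
by default one shared (current-scenario) threshold cuts both scenario
surfaces; `threshold_mode = "per-scenario"` instead rethresholds the
future surface on the ensemble-mean future scores of the model points.

## Variable screening

Stage one computes Pearson correlations over the layer values at the
model's own points (presences plus background — the data the model
actually sees, not the whole raster) and greedily resolves every pair with
|r| above 0.8: the worst-offending pair is located and the member with the
larger mean absolute correlation to all other retained variables is
dropped (a priority ranking, when supplied, overrides this; ties go
alphabetically). Greedy elimination is deterministic and, on the small
variable sets typical here, matches exhaustive search for a maximal valid
subset. Stage two fits a first model, computes permutation importance
(permute a variable jointly across presence + background points, measure
the training-AUC drop, normalize drops to sum to 100), and refits on
variables at or above `importance_cutoff_pct` (default 1%) — the cutoff is
configurable because the judgment it encodes ("the most important
variables") has no canonical value.

## Habitat mapping and the patch rule

Cells at or above the threshold are suitable ("above the threshold" is
implemented inclusively; the threshold value itself must select habitat).
Patches are 8-connected by default — diagonal continuity of montane forest
should not split a patch; 4-connectivity is available. The ecological
filter removes a patch only when it is both below the minimum home-range
area (4 km²) *and* further than a daily dispersal distance (0.5 km,
edge-to-edge: nearest cell-center distance minus one cell size, floored at
0) from the nearest retained patch: a small patch adjoining a large one
remains usable by the animal. The rule is iterated to a fixed point, since
a removal can isolate further patches; the strict two-independent-filters
reading is available via `conjunction = FALSE`.

## Change classification, indicators, elevation contrast

The current/future binary maps partition the valid domain into unchanged,
vulnerable (suitable now, not later), new, and unsuitable cells. With
A_c, A_f, A_fc the current, future and overlapping suitable areas, the
indicators are AC = (A_f − A_c)/A_c, SH_c = (A_c − A_fc)/A_c, and
SH_f = (A_f − A_fc)/A_f (all × 100). Ratios with zero denominators are
reported as undefined (`NA`), matching how published tables print reserves
with no current habitat. The elevation contrast is a Mann-Whitney rank
test over suitable-cell elevations (one value per cell, not per patch):
U of the first group, normal approximation with tie correction and 0.5
continuity correction, and the exact U distribution for the p-value when
the samples are tie-free and n1·n2 ≤ 400.

## The synthetic landscape

The generator exists so every stage is testable offline, and its defaults
are the study conditions the pipeline targets: a 100 × 100 grid of 1-km
cells; six climate layers (half temperature-like, following a lapse rate
on elevation plus smooth noise; half precipitation-like, positive
log-smooth fields); elevation falling north to south with ridge noise; a
forest mask covering 60% of cells; river/road/settlement densities held
constant across scenarios (projections of such variables are not
available in practice); 273 occurrence points at survey scale; 10,000
background points; a 19-reserve network. Spatial autocorrelation comes
from double box-filtering white noise (kernel width
`autocorrelation_range_cells`, default 9) — O(cells) and adequate for
tests, not an exact Gaussian-process draw. The future scenario adds a
temperature anomaly with mean exactly `temperature_delta` (+1.5 °C,
mid-range for a stabilization pathway by mid-century) and scales
precipitation by mean exactly `precipitation_scale` (0.9); the spatial
heterogeneity of both is proportional to the change magnitude, so a null
scenario leaves the future bit-identical to the present and the pipeline
then reports exactly zero change — a useful falsification test.

The generating truth is a logistic-linear surface with a Gaussian optimum
on the first temperature layer (9.5 °C, breadth 1.2 °C), a positive
precipitation effect, and a broad elevation optimum; road and settlement
densities carry no effect and act as decoys for the screening stages. The
niche breadth is a calibration, not an arbitrary aesthetic: presence-vs-
background AUC is bounded above by how concentrated the truth is (with a
broad niche even a perfect model cannot exceed ~0.75), and the defaults
put that ceiling near 0.91 so that the pipeline's recovery benchmark
(mean test AUC > 0.85 and Spearman rho > 0.7 against the truth at 200
presences / 5,000 background) is a real test of the modelling chain
rather than of the generator. Because temperature drives the niche and
temperature follows elevation, additive warming moves the suitable band
upslope (~230 m per +1.5 °C at the default lapse), which the pipeline
must and does detect.

What the generator does *not* emulate: the 19 named bioclimatic variable
formulas, GCM downscaling, land-use change, survey bias beyond the forest
mask, and real patch geometry. Passing the recovery tests therefore shows
the chain is correct and well-calibrated on data satisfying its own
assumptions — it does not validate the model on real survey data.

## Numerical and convention choices

* Rows run north to south, columns west to east; (row, col) indices are
  1-based as everywhere in R; point-in-cell tests are half-open
  (north/west edges belong to the cell).
* ASCII grids are written at full double precision (`%.17g`), so
  write-then-read round-trips bit-exactly, nodata included.
* Reserve cells are assigned by center-in-polygon (boundary counts as
  inside; holes are honored; first-listed reserve wins on overlap), keeping
  every reported area an exact multiple of the cell area; network
  percentages use the union of labeled cells, so overlapping polygons are
  never double-counted.
* Max-SSS ties are detected with a 1e-9 tolerance (exact rational
  sensitivities computed in floating point can differ by ~1e-16) and
  resolved toward the smallest threshold.
* Correlation screening treats a zero-variance layer's undefined
  correlations as non-offending (it is flagged separately rather than
  eliminated by arithmetic accident).

## Problem sizes used by the test-suite experiments

The unit and property tests run on 20 × 20 to 40 × 40 grids with 40-160
presences and a few hundred background points; the recovery experiments
use the full default conditions (100 × 100 cells, 200 occurrences, 5,000
background, 15 replicates) over 3 seeds, and the warming-direction check
uses 5 seeds at 150 occurrences / 2,000 background / 5 replicates. These
sizes were chosen so each experiment's Monte-Carlo spread is well inside
the margins being asserted.

## Known limitations

* No reprojection or resampling: inputs must share the grid, and GeoTIFF
  is not read — convert to ESRI ASCII upstream.
* The maxent implementation targets the model class (linear + quadratic +
  hinge, L1) rather than bit-compatibility with any particular historical
  tool; absolute suitability values differ from other implementations
  even when rankings agree.
* Patch distances are computed between cell centers; sub-cell geometry is
  not represented.
* The Mann-Whitney exact branch requires tie-free data; heavily tied
  elevation rasters fall back to the corrected normal approximation.
* Corridor delineation and multi-GCM/multi-pathway ensembles are out of
  scope.
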
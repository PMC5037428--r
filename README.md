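# dispersim

Tools for asking how much of a gridded species-richness pattern is
explained by **historical dispersal limitation** on top of climate and
topography. The package implements the full analysis chain as reusable,
tested R functions:

* a stochastic **spread simulator** (3×3-neighbourhood cell automaton on a
  suitability raster, compiled core) that turns colonization origins into
  per-cell **accessibility** surfaces, `a(c) = (T + 1 − t_first(c))/(T + 1)`
  averaged over replicates;
* four nested **dispersal scenarios** (DISP1 no barriers; DISP2 desert
  barrier `s = 0`; DISP3 + rainforest `s = 0.2`; DISP4 + arid corridors
  `s = 1` over an `s = 0.5` background), with zonal-mean aggregation to a
  coarse analysis grid;
* a quantile **surface range envelope** SDM with TSS/AUC evaluation and
  richness **stacking** of binary range maps;
* **inference**: Spearman screening, variance partitioning into unique and
  shared R² components, Spearman/VIF collinearity screening, OLS with
  log(x+1) transforms, a second-order polynomial term, z-scored predictors
  and backward-AIC selection, partial residuals;
* **spatial statistics**: k-nearest-neighbour and distance-band weights,
  Moran's *I* with 999-permutation tests, a maximum-likelihood **SAR error
  model** `y = Xβ + u`, `u = λWu + ε` with pseudo-R² (`R²_pred` for the
  trend, `R²_full` for trend + spatial signal), and principal-coordinate
  spatial filters;
* a **synthetic landscape generator** (ocean frame, desert barrier with a
  corridor gap, coastal corridor, rainforest block, climate gradients,
  topographic relief, paleoclimate layers) so every stage is testable
  offline.

## Worked example

```r
library(dispersim)

L <- make_landscape(seed = 1)                       # 120 x 100 fine grid
battery <- scenario_battery(
  L, factor = 2,
  iterations = c(DISP1 = 200, DISP2 = 200, DISP3 = 200, DISP4 = 280),
  replicates = 10, seed = 101)
tab <- assemble_predictor_table(L, battery, factor = 2)

W <- distance_band_neighbors(as.matrix(tab[c("x", "y")]))
tab$RICH <- make_richness_response(
  tab, response_spec(c(DISP4 = 1.5, TEMP_MAX = 0.3, PREC_SEAS = 0.3,
                       TOPO = 0.3), "sar", lambda = 0.6, sigma = 0.8,
                     intercept = 20, seed = 201), W)

fit <- aic_backward(tab, model_spec("RICH", c("DISP4", "TEMP_MAX",
                                              "PREC_SEAS", "TOPO"),
                                    degrees = c(PREC_SEAS = 2)))
sar <- sar_error_fit(design_matrix(tab, fit$spec), NULL, W,
                     moran_weights = knn_neighbors(as.matrix(tab[c("x", "y")])),
                     n_perm = 999, seed = 301)
sar
```

On a typical run of the full pipeline (seed 1) the stages print, in order:
Spearman correlations of richness with the four scenarios `0.054, 0.753,
0.750, 0.757` — the corridor scenario that generated the response ranks
first and the no-barrier null collapses; an OLS fit with R² ≈ 0.71 whose
standardized DISP4 coefficient recovers the generating value (`1.48` for a
true 1.5) but whose residuals are strongly autocorrelated (Moran's *I* =
0.254, permutation *p* = 0.001); and a SAR error fit with `λ̂ = 0.609`
(true 0.6), `R²_pred = 0.707`, `R²_full = 0.771`, after which residual
autocorrelation disappears (Moran's *I* = 0.005, *p* = 0.58). That
OLS-significant → SAR-non-significant shift in Moran's *I*, with the
dispersal term's effect intact, is the qualitative signature the method is
built to detect.

## Layout

```
R/                  grids, synthetic landscapes, dispersal, richness (SDM),
                    inference, spatial statistics
src/                compiled spread kernel (Rcpp)
tests/testthat/     unit, property and end-to-end acceptance tests
scripts/acceptance.R   full-pipeline reproduction script
vignettes/          methods vignette (model, assumptions, design choices)
```
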
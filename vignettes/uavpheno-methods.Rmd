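---
title: "Methods: plot-level multispectral phenotyping with uavpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot-level multispectral phenotyping with uavpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In cereal variety trials, grain yield is the trait of record but is only
known at harvest. Multispectral cameras on UAVs observe each plot many
times through the season, and three families of plot-level features carry
yield information: single-band reflectances, vegetation indices (VIs),
and image texture statistics describing the spatial arrangement of pixel
values within a plot. `uavpheno` implements the full chain from per-date
reflectance orthomosaics and plot polygons to cross-validated
random-forest yield predictions and low/high yield-group classifications,
with flight dates aligned on a thermal-time axis so that seasons are
comparable. Because raw trial imagery is rarely distributable, the
package also contains a synthetic variety-trial simulator that generates
every input the pipeline consumes, with a known ground truth; all tests
run against it.

## Thermal time and agronomic bookkeeping

Flight dates are mapped to cumulative growing degree-days,
$GDD = \sum_{d=1}^{n} T_{mean,d}$ with
$T_{mean,d} = \sum_h \left[(maxT_{d,h} + minT_{d,h})/2 - baseT\right]/24$
over the 24 hours of each day and $baseT = 0\,^\circ\mathrm{C}$, the
winter-wheat convention. Two deliberate choices:

* **No clamping by default.** The daily mean enters the sum as computed,
  so freezing days subtract thermal time. Clamping negative days to zero
  is a common variant but not part of the formula as used here; it is
  available via `clamp = TRUE`.
* **Accumulation starts at sowing.** The axis origin is the sowing date
  passed by the caller, with $GDD$ accruing over each completed day; a
  zero-length span is an empty axis. Counting backwards from harvest
  would merely shift the axis by a constant and is not implemented.

Yields are normalized to 14 % grain moisture on a wet basis
(`mass * (1 - moisture) / 0.86`), and the $k = 3$ varieties with the
lowest/highest mean yield per year are labeled L/H
(`assign_yield_groups()`), with ties broken by variety name so labeling
is deterministic.

## Zonal statistics and vegetation indices

A pixel belongs to a plot iff its **center** lies inside the plot polygon
(points exactly on the boundary count as inside). This is the simplest
reproducible rasterization rule; with plots of thousands of pixels the
choice of rule is immaterial. Band reflectance per plot is the median
over valid in-ROI pixels (mean-of-middle-two for even counts); the
coefficient of variation uses the sample (n−1) standard deviation.

Indices are computed **median-first**: the five plot-median band values
are plugged into the index formulas (DVI, RVI, NDRE, MCARI,
CCII = TCARI/OSAVI). The OSAVI used inside CCII defaults to the variant
$(1+1.16)(NIR-Red)/(NIR+Rededge+0.16)$; the canonical
$(1+0.16)(NIR-Red)/(NIR+Red+0.16)$ is available via
`osavi_variant = "standard"`. Both are kept because the two variants give
materially different CCII values and users may need either for
comparability.

Multi-year data with different cameras are harmonized by a band-name
mapping (e.g. 730 nm and 717 nm both map onto REDEDGE); scenes from a
finer GSD can be aggregated with `resample_average()`, an exact
area-weighted mean that handles non-integer GSD ratios and conserves the
raster mean over aligned regions.

## GLCM texture features

Texture is computed on one base band — RED by default, the band that
typically shows the highest within-plot CV (a ranking
`select_contrast_band()` always reports). The raster is quantized once
per date to `levels = 32` gray levels spanning its 1st–99th percentile
(linear-interpolation quantiles over all valid pixels; values outside are
clipped; the top edge maps to level N−1; a constant raster maps to level
0). A `kernel = 5` sliding window then builds, for each of the
directions 0°, 45°, 90° at distance 1, a **symmetric** co-occurrence
matrix (each pair counted in both orders — Haralick's construction, which
makes the row and column marginals coincide so that a single mean and
variance are well defined), normalized to sum 1. Five statistics are
extracted per direction:

| feature | formula |
|---|---|
| CONTRAST | $\sum P_{ij}(i-j)^2$ |
| CORRELATION | $\sum P_{ij}(i-\mu)(j-\mu)/\sigma^2$ |
| DISSIMILARITY | $\sum P_{ij}\lvert i-j\rvert$ |
| ENERGY | $\sum P_{ij}^2$ |
| HOMOGENEITY | $\sum P_{ij}/(1+(i-j)^2)$ |

Numerical conventions: when $\sigma^2 = 0$ (a window quantized to a
single level) CORRELATION is defined as 0, marking "no linear structure"
without propagating infinities into ROI means. The three directional
feature values are averaged per feature (`angle_mode = "mean_features"`);
pooling the counts before computing features is available as
`"pooled"`. Borders are not padded: any center pixel whose window is
incomplete or touches nodata gets nodata, and ROI means simply exclude
those pixels. The 45° offset is (−1, +1) in (row, col) with row 1 at the
top. The per-plot value is the arithmetic mean of the feature raster over
the ROI.

The sliding-window scan is implemented in C++ (only touched GLCM cells
are visited, so a window costs O(pairs) not O(N²)); the R-level
`glcm_from_window()`/`haralick_features()` operate on single windows, and
the test suite checks the compiled scan per-pixel against an exhaustive
enumeration oracle written independently in R.

## Temporal assembly

Three strategies turn the per-date feature table into design matrices:

1. **single** — the feature at one date (one column);
2. **smoothed** — the same, after per-plot P-spline smoothing on the GDD
   axis: penalized cubic B-splines with one basis function per
   observation (capped at 40), second-order difference penalty, smoothing
   parameter by GCV (`mgcv::gam(..., bs = "ps")`). Those are the
   documented core of the standard plot-phenotyping smoothers; since the
   exact settings used elsewhere are rarely printed, the smoothing
   parameter is exposed (`sp`) for sensitivity runs. With `sp = 0` the
   fit is an unpenalized regression-spline interpolant — a projection,
   hence exactly idempotent, which the tests exploit; with GCV-chosen
   penalties smoothing is only approximately idempotent, as for any
   ridge-type smoother. Series with fewer than 4 points are passed
   through unsmoothed with a warning; missing observations are ignored in
   fitting and imputed in the output.
3. **window** — the feature at the previous, current and following date
   (width 3). At the first and last date the missing neighbor is clamped
   to the nearest existing date (duplicated column), so every date is
   evaluable and season-long metric curves have no holes; the stricter
   `drop_endpoints = TRUE` alternative drops those dates instead.
   Missing data are handled complete-case per matrix.

## Evaluation

Random forests (500 trees) are evaluated by 10-fold cross-validation
repeated 3 times (30 held-out evaluations), with fresh random partitions
per repeat; classification folds are stratified by class so both classes
appear in every fold at n = 24 (the fold count must not exceed the
smallest class). With more than one predictor, mtry is chosen per
training fold from 1…p by minimizing the out-of-bag error of a forest fit
per candidate on that training fold; OOB estimation is the forest's
built-in, essentially free resampling estimate, and keeps the sweep's
~10⁵ forest fits tractable, whereas a nested inner CV (available via
`cv_config(tune = "inner_cv")`) multiplies the fit count by the inner
fold × grid factor for little gain at these sample sizes. Remaining
hyperparameters follow the `randomForest` defaults (regression node size
5, classification 1, bootstrap with replacement).

Metrics: RMSE $= \sqrt{\sum_i (x_i - y_i)^2 / n}$; R² is the squared
Pearson correlation between observed and predicted (bounded in [0, 1]);
accuracy = (TP + TN)/total. R² as squared correlation is used because it
is the convention that pairs naturally with correlation-based feature
screening; it does not penalize calibration offsets, which RMSE captures.
Supporting analyses: per-date Pearson correlation matrices of all 15
features plus yield, and per-date Welch t-tests between the H and L
groups (the degenerate all-equal case returns t = 0, p = 1 rather than
erroring).

All randomness flows from configuration seeds: `cv_config(seed)` seeds
each evaluation, and `run_experiment()` derives one sub-seed per
feature × date × strategy × task combination, so the full sweep is
bit-reproducible.

## The synthetic trial

`simulate_trial()` emulates a randomized complete block design — 19
varieties × 4 replicates of 10 m × 1.85 m plots by default, each
replicate one field column with its own random variety order — observed
on a 19-date flight schedule spanning 300–1700 GDD. Components:

* **Weather**: an annual sinusoid (mean 8 °C, amplitude 10 °C, coldest
  mid-January) plus AR(1) daily noise, expanded to hourly max/min pairs
  whose diurnal cycle averages out exactly in the daily mean. A typical
  season accumulates ~1800–2000 GDD from an October sowing to an August
  harvest, comfortably covering the flight schedule.
* **Canopy tracks**: green cover $f$ rises logistically in GDD (midpoint
  550, scale 90), senescence $s$ follows later (midpoint 1350, scale 70),
  both shifted per variety (SD 40 GDD, plus a 10-GDD plot jitter).
  Chlorophyll $c_i$ scales with a standardized plot-level latent linked
  to the variety yield effect.
* **Reflectance**: per pixel, an endmember mixture
  $f_{px}[(1-s)\,\mathrm{leaf}(c) + s\,\mathrm{senesced}] +
  (1-f_{px})\,\mathrm{soil}$, where $f_{px}$ modulates the plot's cover
  by an across-row sinusoid (0.125 m sowing rows, visible only while the
  canopy is open) and the result carries multiplicative lognormal speckle
  whose amplitude shrinks toward canopy closure. Chlorophyll linearly
  deepens RED and REDEDGE absorption. Endmember values are chosen to
  reproduce the qualitative band dynamics of a wheat season (RED falls to
  a minimum near booting–flowering, then rises with senescence), not
  radiometric truth.
* **Yield**: $y_i = \beta_0 + q_v + \beta_1 (G_i - G_{ref}) +
  \varepsilon_i$ with variety effects $q_v \sim N(0, 35)$ g m⁻², the
  schedule-mean green-canopy term $G_i = \overline{f(1-s)c}$, slope
  $\beta_1 = 400$, residual SD 50 g m⁻², and $\beta_0 = 535.5$ g m⁻²
  anchored at a field-realistic trial mean. Under the defaults, plot
  yields average ≈ 535 g m⁻² with SD ≈ 75–100 g m⁻² and L/H groups
  emerge from the variety effects. Fixed variety effects can be supplied
  (`variety_effects`) when an experiment prescribes a group separation.
* **Phenology**: BBCH-like ratings are interpolated from GDD anchors
  (tillering mid-20s near 500 GDD through grain filling in the 80s near
  1700 GDD), shifted per plot, and reported per flight date, giving the
  stage labels (TI, SE, BO, HE, FL, EF, GF — by BBCH decades, the
  boundary rule being configurable only in the sense that the mapping
  function is exposed).

The default render uses a 0.125 m GSD (≈ 15 × 80 px per plot, a ~350 ×
370 px field) so a full 19-date trial renders in a couple of seconds; at
that GSD the 0.125 m row sinusoid is aliased rather than resolved, and
the cover-dependent speckle carries the texture signal. Rendering at
0.025 m resolves the rows explicitly (the tests exercise this) at ~25×
the pixel count.

**What the simulator does not emulate** — and hence what green tests do
not certify about field data: radiative transfer and BRDF effects,
weather-driven stress events, lodging, spatial field trends and
neighbor effects, registration error between dates, and the empirical
covariance structure of real multispectral noise. Passing tests show the
pipeline's algebra, bookkeeping and statistical machinery are correct
and that it recovers structure it is built to detect; they do not
reproduce any field study's absolute error levels.

## Problem sizes used by the tests

Unit tests use 6-variety × 2-replicate trials with 2–5 flight dates and
20×20 texture oracles. The end-to-end reproducibility check sweeps 15
features × 6 dates × 3 strategies × 2 tasks (540 evaluations) on an
8-variety × 4-replicate trial at the full 500-tree, 10-fold × 3-repeat
setting; recovery and window-combination properties use 76-plot trials
over 5 seeds. The acceptance script reruns a default 76-plot trial and
reports its headline quantities.

## Known limitations

* GeoTIFF I/O goes through a scaled 32-bit TIFF plus JSON sidecar (about
  2 × 10⁻¹⁰ absolute resolution at reflectance scale); CRS metadata is
  not interpreted — scenes and polygons must already share a planar
  coordinate system. Shapefile input is not supported; use GeoJSON.
* Polygons are simple rings; multi-polygons and holes are not supported.
* The evaluation sweep is single-threaded by design (deterministic given
  a seed); parallelism across combinations would break bit-for-bit
  reproducibility of the per-combination seed stream as implemented.
* Correlation-matrix entries for zero-variance features are NA rather
  than dropped; downstream consumers must handle them.
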
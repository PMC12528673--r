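---
title: "Methods: land suitability, weather forecasting and rule-based crop advice"
author: "cropsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land suitability, weather forecasting and rule-based crop advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cropsense implements a hybrid crop-advisory pipeline for precision
agriculture: spectral indices computed from Sentinel-2-like surface
reflectance feed a patch-based convolutional classifier of agricultural land
suitability; a recurrent (LSTM) sliding-window model forecasts daily weather;
and a deterministic IF–THEN rule engine combines the two into dated crop
recommendations. Every stage can be exercised end-to-end on synthetic data
with known ground truth, which is how the package tests itself.

This vignette explains the models, their assumptions, the tunable parameters
with their defaults, the synthetic-data generator, and the numerical and
design choices made where the design was genuinely open.

## Spectral indices

Six indices are computed from six bands under the standard Sentinel-2
mapping Blue = B02, Green = B03, Red = B04, NIR = B08, narrow NIR = B8A,
SWIR = B11:

* `NDVI = (NIR - Red)/(NIR + Red)` — green-vegetation density and health,
* `NDWI = (Green - NIR)/(Green + NIR)` — surface/plant water,
* `MOISTURE = (narrowNIR - SWIR)/(narrowNIR + SWIR)` — canopy/soil moisture,
* `EVI = G (NIR - Red)/(NIR + C1 Red - C2 Blue + L)` — gain- and
  aerosol-corrected vegetation index,
* `NDSI = (Green - SWIR)/(Green + SWIR)`,
* `GNDVI = (NIR - Green)/(NIR + Green)` — chlorophyll-sensitive NDVI variant.

Two definitional choices deserve a note. First, an NDVI variant with
numerator and denominator swapped — `(NIR + Red)/(NIR - Red)` — circulates
in some descriptions; it is the reciprocal of the standard index, unbounded
near `NIR = Red`, and inconsistent with the usual reading that high NDVI
means healthy vegetation. `compute_index()` therefore implements standard
NDVI and exposes the literal reciprocal form behind the `ndvi_as_printed`
flag rather than silently dropping it. Second, EVI's constants are not
universal; the defaults `G = 2.5, C1 = 6, C2 = 7.5, L = 1` are the standard
MODIS/Sentinel-2 values and are overridable through `evi_constants()`.

Numerical conventions: pixels whose index denominator is exactly zero are
masked, never assigned an arbitrary value, and masks propagate through
stacking (a stacked pixel is valid only if all six channels are valid).
Before stacking, each index layer is min–max normalized to [0, 1];
`minmax_normalize()` returns the parameters it used so that inference can
reuse training statistics, and a constant layer maps to all zeros with a
`degenerate` flag instead of dividing by zero. EVI, unbounded in principle,
is normalized by min–max like every other channel rather than assumed to
lie in [-1, 1].

## Land-suitability classifier

Land is classified into three classes — NOT_SUITABLE (0), LOW (1), HIGH (2)
agricultural preference — from the six-channel index stack. The classifier
is a compact convolutional network over square patches centred on each
pixel: three convolutional blocks with 32, 64 and 128 filters (3×3 kernels,
'same' padding), each block ReLU → 2×2 max-pooling → batch normalization,
then two dense layers (64, 32 units) with dropout 0.3 after the first, and
a 3-way softmax. Training uses Adam (learning rate 0.001), categorical
cross-entropy, a stratified 80/20 train/validation split by pixel, and
early stopping on validation loss (patience 5) with best-weight restore.
The convolution, pooling, batch-norm and dense layers are implemented in
vectorized base R inside the package and are verified against
finite-difference gradients in the test suite.

Design choices where the design was open:

* **Patch size.** "Per-pixel classification" and "pooling layers" pull in
  opposite directions: pooling needs spatial extent. The default is 9×9
  patches labelled by their centre pixel, which supports all three pooling
  steps (9 → 4 → 2 → 1); patch size is configurable down to 1×1, and
  pooling disables itself automatically whenever the running spatial extent
  falls below 2.
* **Edges.** Reflection padding (mirror without repeating the edge pixel)
  keeps one sample per pixel and full-coverage prediction maps.
* **Training-set size.** `max_train_samples` defaults to 1152 — 36
  optimizer steps per epoch at batch size 32 — drawn stratified from the
  training split; validation keeps the full 20%.
* **Determinism.** Initialization, shuffling and dropout all run under a
  seed derived from the config, so identical configs reproduce identical
  models and maps.

On a zero-noise synthetic scene the three classes are perfectly separable
in index space, so held-out accuracy is expected above 0.95; a
label-shuffled control collapses to chance level (between uniform 1/3 and
the majority-class share), which guards against information leaking from
the patch extractor into the labels.

## Weather forecaster

Daily temperature (°C), relative humidity (%), precipitation (mm/day) and
station pressure are forecast jointly. Features are min–max scaled on the
training span only; a window of `window_length = 7` consecutive days (5–7
is the sensible range) feeds an LSTM with 64 units; a sigmoid output layer
predicts the next day's scaled 4-vector; training minimizes mean squared
error with Adam (initial learning rate 0.005, batch 32, up to 50 epochs),
dropout 0.2 on the final hidden state, a chronological 80/20 split (the
last fifth of days is the validation span — never shuffled, so no temporal
leakage), early stopping (patience 12) and learning-rate halving after 4
stale epochs down to 1/25 of the initial rate. The fine-convergence phase
provided by the schedule matters: multi-day forecasts are produced by
iterative roll-out (each predicted day is appended to the window to predict
the next), and small one-step biases otherwise compound into a visible
level offset over 30 days.

Two further choices:

* **Output calibration (MOS).** After training, a per-variable linear map
  is fitted from the one-step validation predictions to the observed scaled
  values (classical model-output-statistics correction) and applied at every
  roll-out step. This removes most of the systematic level bias a recursive
  forecast otherwise locks onto; it uses only training-period data.
* **Physical bounds.** Forecast humidity is clipped to [0, 100] and
  precipitation floored at 0 on read-out; the fed-back scaled state is kept
  near the unit box to prevent runaway.

The skill reference is the persistence baseline — repeat the last observed
day over the whole horizon. On synthetic seasonal series (annual amplitude
8 °C, daily noise 1 °C, three years of training), the roll-out forecast's
30-day temperature RMSE sits close to the daily-noise floor (≈ 1 °C),
whereas persistence carries the last day's noise and any seasonal trend, so
the trained model wins in most seeded repetitions. A genuine limitation:
the 7-day window contains no calendar information, so on steep seasonal
slopes the window cannot fully disambiguate rising from falling phases and
multi-week trend-following is weak; near seasonal extrema (where the
package's default study period ends) the forecaster's advantage is its
noise averaging. Missing days are rejected, not imputed — the windowing
contract assumes contiguity.

## Rule-based crop recommendation

The rule engine is deterministic IF–THEN matching of a daily weather
reading against per-crop admissible ranges, all closed intervals:

| crop | temperature (°C) | humidity (%) | precipitation (mm/day) | salinity tolerance |
|-----------|-------|-------|----------|--------|
| Wheat | 10–20 | 50–70 | 0.1–1.0 | Low |
| Rice | 20–30 | 70–90 | 3.0–10.0 | Medium |
| Maize | 18–27 | 60–80 | 1.0–3.0 | Medium |
| Chickpea | 15–25 | 40–60 | 0.0–1.0 | High |
| Sugarcane | 21–35 | 60–80 | 2.0–5.0 | Medium |

A crop is recommended only when the reading lies in all three of its ranges
*and* the land class reaches the crop's `required_land_class` (default HIGH
for every crop — the spatial and temporal conditions must both hold). Every
matching crop is returned, in rule-set order; when nothing matches, the
verdict is the literal string `"Unsuitable conditions"`. An optional
ranking orders multiple matches by the normalized distance of the reading
to each crop's range midpoints, but no priority scheme is invented beyond
that. A narrative single-rule alternative for rice (22–30 °C, humidity
above 60%, precipitation unconstrained) ships as `text_rice_rule()`; the
systematic table above is canonical where the two disagree.

Salinity tolerance is carried as metadata only: the pipeline computes no
salinity measurement (no salinity index is implemented, as no defensible
formula is available for the band set), so no rule thresholds on it. The
same applies to rice's standing-water requirement, which is not expressible
as a precipitation interval.

## Synthetic data

`generate_scene()` draws one reflectance raster per band on a common grid:
each pixel takes its class's mean signature plus i.i.d. Gaussian noise
(default sd 0.01), clipped to [0, 1]. The default signatures emulate dense
irrigated cropland, sparse/stressed vegetation and dry bare soil, with
implied NDVI ≈ 0.84, 0.35 and 0.08 — well separated, by construction
perfectly separable at zero noise. The default layout is a seeded Voronoi
tessellation (12 seed points, each of the three classes guaranteed at least
one region), giving contiguous patches of realistic scale for the patch
classifier. Band wavelengths and nominal resolutions are carried as
metadata only; all bands share one grid, emulating imagery already
resampled to a common 10 m resolution.

`generate_weather()` emulates an arid North-African agricultural climate:
temperature is a sinusoid with mean 21 °C and amplitude 8 °C, phased so the
minimum falls in mid-January, plus Gaussian noise (sd 1 °C); humidity is a
base of 60% minus 1.5 %/°C times the temperature anomaly plus noise (sd
8%), clipped to [0, 100]; precipitation is a Bernoulli–exponential mixture
(wet-day probability 0.15, mean wet-day rainfall 1 mm/day) — mostly dry
days with occasional light rain; pressure is Gaussian around 100.8 with sd
0.3 in the unit of the station records (the pipeline never thresholds on
pressure, so the unit is carried, not interpreted).

What the generator deliberately does **not** emulate: clouds, shadows and
atmospheric effects (scenes behave as already-corrected surface
reflectance), spatial autocorrelation of reflectance noise, mixed pixels at
class boundaries, weather fronts and multi-day persistence of anomalies,
and any real geography. Passing tests on these data therefore demonstrate
that the algorithms are implemented correctly and behave as designed under
controlled conditions — not that the trained models would transfer to real
Sentinel-2 scenes or station records.

## Numerical choices and degenerate inputs

* Zero index denominators → masked pixels; masks are unioned across
  channels at stacking; stacking never unmasks a pixel.
* Constant (degenerate) normalization → all zeros plus a flag and warning,
  both for index layers and forecaster features.
* Precision/recall/F1 with a zero denominator → 0 with a warning
  (deterministic, standard convention); multiclass accuracy is
  trace/total, which coincides with the binary TP/TN form in the
  one-vs-rest view.
* Max-pooling ties break toward the first position scanned; trailing odd
  rows/columns are dropped (floor semantics).
* All stochastic stages run under seeds derived from one global seed, and
  artifacts are reproducible byte-for-byte.

## Problem sizes

The test-suite and acceptance runs use sizes chosen to exercise every code
path at desk scale: 64×64 scenes (4096 pixels) for classifier recovery,
1152-sample training caps (36 steps/epoch at batch 32), three simulated
years of daily weather with a 30-day verification horizon, five seeded
repetitions for the forecaster-vs-persistence comparison, and 10,000-case
random sweeps for the rule-engine and metric oracles. Structural unit tests
run on smaller grids (10–24 pixels a side) and lighter networks.

## Limitations

* The classifier and forecaster are desk-scale reimplementations in base R;
  they are exact in their mathematics (gradient-checked) but not tuned for
  large rasters or long series.
* No atmospheric correction, cloud masking or resampling is performed;
  inputs are assumed analysis-ready on a common grid.
* The rule engine is crisp: a reading 0.01 mm/day outside a precipitation
  range is rejected outright. Fuzzy membership is a natural extension and
  deliberately out of scope.
* Forecast skill claims are relative to persistence on synthetic seasonal
  data; no claim is made about skill on real station records.
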
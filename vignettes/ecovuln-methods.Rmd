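---
title: "Methods: sliding-window vulnerability, regime classification and driver thresholds"
author: "EcoVuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window vulnerability, regime classification and driver thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EcoVuln)
```

## The model

EcoVuln quantifies how vulnerable a vegetated ecosystem is to climatic
disturbance, pixel by pixel and year by year, from three co-registered
monthly grids: NDVI (vegetation condition), mean temperature and total
precipitation. The analysis has three stages.

### Stage 1: windowed exposure–sensitivity–resilience index

Within each five-year window (advanced one year at a time; a 1983–2022
record yields 36 windows assigned to their center years 1985–2020), the
three monthly series of each pixel are deseasonalized against the
within-window month-of-year climatology and z-scored, and the standardized
NDVI anomaly is regressed on the contemporaneous climate anomalies and its
own one-month lag:

$$N_t = \alpha\,T_t + \beta\,P_t + \gamma\,N_{t-1} + \varepsilon_t .$$

$\alpha$ and $\beta$ measure the strength of the immediate vegetation
response to temperature and precipitation; $\gamma$ measures persistence —
how slowly the vegetation returns to baseline after a perturbation. The
coefficients are min–max normalized across all valid pixels of the window
and combined as

$$EI = \alpha_n + \beta_n, \qquad
  SI = \alpha_n T_{norm} + \beta_n P_{norm}, \qquad
  RI = 1 - \gamma_n, \qquad
  VI = \frac{EI \cdot SI}{1 + RI},$$

where $T_{norm}$ and $P_{norm}$ are the min–max-normalized window means of
raw temperature and precipitation. Exposure ($EI$) is total climatic
coupling, sensitivity ($SI$) weights that coupling by the local
hydrothermal state, resilience ($RI$) is the complement of persistence, and
the vulnerability index $VI \in [0, 4]$ grows with exposure and sensitivity
and is damped by resilience.

### Stage 2: interannual regime classification

Each pixel's annual $VI$ series (36 values) is summarized by its
coefficient of variation (binned `<20`, `20–30`, `>30` percent) and
classified into one of four regimes — `no_trend`, `linear_increase`,
`linear_decrease`, `abrupt` — by comparing three candidate models:

* simple linear regression (slope t-test; least-squares AIC with $k = 3$);
* continuous two-segment piecewise regression with the break chosen by
  exhaustive RSS search (AIC with $k = 5$);
* the Pettitt change-point test, with a two-mean step model supplying an
  AIC ($k = 4$) so the nonparametric candidate can enter the comparison.

If no candidate is significant the pixel is `no_trend`; if exactly one is,
it wins; if several are, the lowest AIC wins with ties going to the simpler
model. A winning turning point within five years of either series end is
re-evaluated with the plain linear fit (significant slope gives a linear
class, otherwise `no_trend`), because a "break" that close to the boundary
cannot be distinguished from an edge artifact. Interior abrupt winners are
labeled I–D or D–I by their segment-slope signs; abrupt pixels are binned
into five-year turning intervals.

### Stage 3: driver analysis

Annual driver covariates (precipitation, evapotranspiration, aridity,
vapor pressure deficit, humidity, soil moisture, temperature extremes,
radiation, grazing intensity, nighttime light) are paired with the
pixel-year $VI$. Features with variance inflation factor $\ge 10$ are
removed one at a time (highest first, recomputing after each removal); the
retained set feeds a gradient-boosted regression (80/20 seeded split,
hyperparameters chosen by cross-validated grid search on the training split
only, metrics reported on the untouched test split). Exact tree-SHAP
attributions give per-feature importance shares (mean |attribution|,
normalized to 100%), and partial-dependence curves for the top features are
reduced to threshold readouts by BIC-selected piecewise-linear fits. The
whole chain is repeated per stable ecosystem class.

## Key parameter choices

| Parameter | Default | Why |
|---|---|---|
| window length / step | 5 yr / 1 yr | 60 monthly observations per fit; annual index resolution |
| significance level | 0.05 | conventional; used by all three trend tests |
| `minSegment` | 5 yr | matches the 5-year boundary-exclusion distance |
| `boundaryYears` | 5 yr, inclusive | turning years in `[first, first+5]` or `[last-5, last]` re-evaluated |
| VIF cutoff | 10 | conventional multicollinearity threshold |
| split fraction | 0.8 | standard 80/20 train/test |
| hyperparameter grid | trees {100, 300, 500}, depth {3, 5, 7}, learning rate {0.05, 0.1}, subsample {0.8, 1.0} | small, standard desk-scale grid; 5-fold CV |
| PDP grid | 50 points, 1st–99th percentile | robust to range outliers |
| CV bins | 20%, 30% | low / moderate / high variability |

## Design choices where the method was genuinely open

**Deseasonalize before z-scoring (default on).** "Standardized anomalies"
leaves the anomaly baseline open. We subtract the within-window
month-of-year mean first so the regression relates anomalies rather than
shared seasonal cycles, and each 60-month window is self-contained; raw
z-scoring is available via `deseasonalize = FALSE`.

**Min–max scope (default per-window, cross-pixel).** Normalizing
$\alpha, \beta, \gamma$, $T_{norm}$ and $P_{norm}$ across pixels *within*
each window keeps every annual map internally comparable, at the cost of
absorbing any drift shared by all pixels (a spatially uniform change in
coupling cancels out of the normalized values). The pooled-across-windows
mode (`normalizationScope = "pooled"`) preserves such common drift and
therefore reads interannual change differently; the synthetic tests that
plant a landscape-wide regime shift use it. Neither choice is neutral, and
the scope materially affects interannual trends — both are retained.

**Intercept in the window regression.** Standardized inputs are centered,
so the intercept is immaterial; it is kept as insurance against numerical
drift. Negative raw coefficients are not truncated before min–max scaling —
the scaling maps the most negative value to 0 and truncation would discard
rank information.

**Piecewise significance by separate per-segment t-tests.** The break is
chosen by an RSS search over all admissible break years, and t-statistics
read off the hinge-model covariance at the selected break are inflated by
that search (on i.i.d. noise they fire at roughly 7% per test instead of
the nominal rate). Each segment's slope is therefore re-fit and t-tested on
that segment's own observations, which brings the piecewise candidate's
null firing rate to about 1.5% and keeps the cascade's joint type-I rate
near 9%. An abrupt classification additionally requires the two significant
segment slopes to have opposite signs; same-sign fits fall through to the
linear re-evaluation.

**Pettitt significance and AIC.** The asymptotic approximation
$p = 2\exp(-6K^2/(n^3+n^2))$ is used as is. Simulation at $n = 36$ puts its
true null rejection rate near 0.023 at nominal 0.05 — the approximation is
conservative at this series length. We retain it: it is the standard form,
and its conservatism partly offsets the selection optimism of the other
candidates in the cascade; replacing it with a calibrated (permutation)
p-value would inflate the cascade's joint false-positive rate. Because the
Pettitt test is nonparametric, its AIC entry is computed from a two-mean
step model split at the change point — the minimal likelihood that makes
the cross-model AIC comparison well-defined. A Pettitt winner is only
labeled abrupt when its two segments carry significant opposite trends;
a pure level step is re-read by the linear rule.

**Threshold readout.** The source analyses report PDP thresholds without an
algorithm. We fit continuous piecewise-linear models with 0–2 breaks to
each curve, select the break count by BIC, and merge breaks closer than two
grid steps (a steep transition between plateaus is one threshold, not two).
The RSS entering the BIC is floored at a scale-aware epsilon so that
numerically exact fits are compared on parameter count alone. The middle
segment of a two-break fit may be arbitrarily short — a sharp step *is* the
phenomenon being read out — while the outer segments need `minSegment`
grid points of support.

**PDP mode.** The default traces the response with the other features held
at their sample means (`"at_means"`), matching the stated construction of
the emulated analysis; the conventional averaged-over-data profile is
available as `"averaged"`. The two agree for additive responses.

**Driver sampling unit.** Pixel-years are pooled by default; a
per-pixel-mean mode exists in the generator. The pooled unit matches the
per-sample SHAP readouts the analysis produces.

## What the synthetic generators emulate — and what they do not

`generateLandcover` plants an annual class-map stack with an exact fraction
of mid-series conversions; `generateClimateVeg` builds sinusoidal
climatologies plus white-noise climate anomalies and evolves the NDVI
anomaly by the first-order recursion above (24-month burn-in, stationarity
enforced by $|\gamma| < 1$), optionally drifting the generating
coefficients linearly or piecewise over years — for a whole landscape or
for a seeded fraction of pixels; `generateViSeries` plants constant, linear
or broken-stick annual series; `generateDriverTable` draws the 13 candidate
drivers on realistic natural-unit ranges, regenerates five of them (TEM,
PET, AI, RHU, NTL) as strongly collinear children of the other eight so
that VIF screening removes a known set, and builds the target from planted
flat/linear/step/V/plateau responses at signal-to-noise 10:1 by default.
Every generator takes an explicit seed, restores the caller's RNG state and
returns its ground truth.

Real data differ in ways the generators deliberately ignore: spatial
autocorrelation of noise fields (pixels here are independent), sensor
artifacts and gaps, non-sinusoidal seasonality, time-lagged and cumulative
climate effects, and drivers that are causally coupled to the vegetation
rather than drawn independently. Passing tests therefore demonstrate that
the estimators recover what was planted under the stated noise model — not
that the index or the thresholds are ecologically correct for any
particular region.

## Numerical conventions and degenerate inputs

* Grids are row-major from the top-left, north-up; pixel order is
  column-major over the `row x col` grid everywhere.
* `NA` is the nodata sentinel; any nodata month invalidates that
  pixel-window, and invalid pixel-windows emit `NA` downstream rather than
  raising.
* Zero-variance series (a pure climatology) are flagged invalid at
  standardization; degenerate min–max ranges collapse to 0.5 with a
  warning; zero-mean series are excluded from CV binning.
* Ties in the Pettitt statistic contribute `sign(0) = 0`; VIF ties at the
  maximum drop the later column first; equal AICs go to the simpler model.
* AIC is the least-squares form $n\log(\mathrm{RSS}/n) + 2k$ with $k$
  counting mean parameters plus the variance; the small-sample correction
  is off by default (switchable in principle by post-processing the
  returned RSS values).

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: coefficient recovery on
500 pixel-windows of 60 months; 1,000-case algebra and change-point
cross-checks; 200-replicate classification simulations ($n = 36$ years);
driver tables of 1,000–5,000 pixel-years with 10-seed end-to-end threshold
recovery; and a full 20 x 20-pixel, 480-month pipeline run with a rerun
determinism check. These sizes were chosen so each property estimate is
stable at the asserted tolerance while the whole battery stays interactive
on a single CPU.

## Known limitations

* One break per series; no Mann–Kendall/Sen alternatives; no
  field-significance correction across pixels.
* No reprojection: inputs are assumed co-registered on one grid.
* The vulnerability formulation is the fixed $EI \cdot SI / (1 + RI)$
  composite; alternative weightings are out of scope.
* Grid I/O is matrix/CSV-based; the geometry metadata carries cell size and
  origin, but no coordinate reference system handling is attempted, and
  area percentages use planar pixel counts (no geodesic correction).

## A worked miniature

```{r mini, eval = FALSE}
spec <- landscapeSpec(12, 12, conversionFraction = 0.05,
                      years = 1983:2022, seed = 42)
proc <- processParams(trendSpec = list(type = "piecewise", breakYear = 2005,
                                       slope1 = -0.006, slope2 = 0.006,
                                       fraction = 0.6))
cfg <- pipelineConfig(landscape = spec, process = proc, seed = 42,
                      outputDir = "ecovuln-run")
res <- runPipeline(cfg)
res$areas          # CV / trend / pattern / timing percentages
res$turningTable   # five-year turning intervals
importancePercent(res$drivers$overall)
```
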
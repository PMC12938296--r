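# EcoVuln

EcoVuln is an R package for analysts of long-term vegetation–climate
records who want to ask three questions of a gridded monthly NDVI /
temperature / precipitation archive: *how vulnerable is each pixel's
ecosystem, year by year?* — *did that vulnerability drift, or flip regime
at a turning point?* — and *which environmental or anthropogenic drivers
push it, and past what thresholds?* Everything runs end-to-end on synthetic
landscapes with known ground truth, so every stage of the method is
testable without any external download.

## The method

**Windowed vulnerability index.** Within each five-year sliding window
(one-year step; 1983–2022 gives 36 windows, centered 1985–2020), each
pixel's monthly series are deseasonalized and z-scored, and the NDVI
anomaly is regressed on the climate anomalies and its own lag,

```
N_t = α·T_t + β·P_t + γ·N_{t−1} + ε_t
```

The coefficients, min–max normalized across pixels within the window,
combine into exposure `EI = α + β`, sensitivity
`SI = α·T_norm + β·P_norm` (with `T_norm`, `P_norm` the normalized window
means of raw temperature and precipitation), resilience `RI = 1 − γ`, and
the vulnerability index

```
VI = EI · SI / (1 + RI)
```

**Regime classification.** Each pixel's annual VI series is classified as
`no_trend`, `linear_increase`, `linear_decrease` or `abrupt` by comparing
simple linear regression, continuous piecewise regression and the Pettitt
change-point test under an AIC cascade, with a boundary rule that
re-evaluates turning points within five years of either series end. Abrupt
pixels are labeled I–D or D–I from their segment slopes and binned into
five-year turning intervals.

**Driver thresholds.** Candidate drivers are screened by iterative VIF
(cutoff 10), the survivors feed a gradient-boosted regression (seeded
80/20 split, cross-validated grid search), exact tree-SHAP attributions
rank the drivers, and BIC-selected piecewise-linear fits read thresholds
off the partial-dependence curves — overall and per stable ecosystem
class.

## Worked example

```r
library(EcoVuln)

spec <- landscapeSpec(12, 12, conversionFraction = 0.05,
                      years = 1983:2022, seed = 42)
proc <- processParams(trendSpec = list(type = "piecewise", breakYear = 2005,
                                       slope1 = -0.006, slope2 = 0.006,
                                       fraction = 0.6))
cube <- generateClimateVeg(spec, proc)     # 144 pixels x 480 months + truth
vi   <- buildViSeries(cube, normalizationScope = "pooled")
cls  <- classifyTrends(vi)
cls
#> TrendClassification: 144 pixels
#>   abrupt           38
#>   linear_decrease  25
#>   linear_increase  22
#>   no_trend         59
binTurningYears(cls)
#>         bin count areaPercent
#> 1 1990-1995     9    6.250000
#> 2 1995-2000     8    5.555556
#> 3 2000-2005     6    4.166667
#> 4 2005-2010     3    2.083333
#> 5 2010-2015    12    8.333333
```

A 60% fraction of pixels was given a decrease-then-increase coefficient
drift breaking in 2005; the classifier reports `abrupt` as the largest
single class with turning years spread around the planted break (the rest
of the drift is absorbed as linear segments or lost in noise — the
windowed estimates are themselves noisy).

```r
dt <- generateDriverTable(driverSpec(), 3000, seed = 42)
da <- analyzeDrivers(dt$features, dt$target,
                     grid = data.frame(nrounds = 150L, max_depth = 4L,
                                       eta = 0.1, subsample = 1.0),
                     seed = 42)
da
#> DriverAnalysis: 8 retained features
#>   held-out R2 0.986, RMSE 0.0503, MAE 0.0378
#>   top importance: GI 34.2%, SM 30.1%, VPD 26.7%, PRE 8.0%
lapply(thresholds(da), round, 2)
#> $GI
#> [1] 0.88
#> $SM
#> [1] 79.27
#> $VPD
#> [1] 0.39
#> $PRE
#> [1] 651.66
```

The default driver table plants a grazing-intensity step at 0.90 SU/ha, a
soil-moisture plateau at 79 mm, a vapor-pressure-deficit step at 0.39 kPa
and a gentle precipitation plateau at 705 mm, and builds five of the 13
candidates as collinear children of the others; the chain drops exactly
those five (TEM, PET, AI, RHU, NTL), ranks the planted drivers on top and
reads the thresholds back within a few percent (the shallow PRE knee is
hardest and lands lowest).

`runPipeline(pipelineConfig(...))` chains every stage — land cover, cube,
stable-pixel mask, VI, classification, area summaries, per-ecosystem driver
analysis — and writes tidy CSV/JSON artifacts plus a run manifest. A thin
command-line wrapper is included:

```sh
Rscript inst/scripts/run-pipeline.R --config config.yaml
```

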
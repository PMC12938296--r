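Package: EcoVuln
Title: Sliding-Window Ecosystem Vulnerability Indices, Regime-Shift
    Classification, and Driver Threshold Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a per-pixel exposure-sensitivity-resilience ecological
    vulnerability index (VI) from monthly NDVI, temperature and precipitation
    grids using five-year sliding-window regressions; classifies each pixel's
    annual VI series into no-trend, linear, or abrupt (turning-point) regimes
    by comparing simple linear regression, continuous piecewise regression and
    the Pettitt change-point test under an AIC cascade; and quantifies
    environmental and anthropogenic drivers of interannual VI variation with
    variance-inflation-factor screening, gradient-boosted regression, SHAP
    attribution and partial-dependence threshold detection. A synthetic-data
    module generates landscapes, climate-vegetation cubes, annual series and
    driver tables with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
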
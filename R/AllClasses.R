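#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowData colData
NULL

## ---------------------------------------------------------------------------
## Specification objects for the synthetic-data generators
## ---------------------------------------------------------------------------

#' Landscape specification for synthetic land-cover generation
#'
#' Describes the raster geometry, land-cover composition and conversion
#' regime of a synthetic landscape. Class fractions are given over the five
#' ecosystem classes plus nodata and must sum to one; `conversionFraction`
#' is the proportion of *vegetated* pixels whose class switches once, at a
#' random year, mid-series.
#'
#' @slot nRows,nCols Grid dimensions (pixels).
#' @slot classFractions Named numeric over
#'   `c("cropland","forest","shrubland","grassland","wetland","nodata")`,
#'   summing to 1.
#' @slot conversionFraction Proportion in `[0, 1)` of vegetated pixels that
#'   change class mid-series.
#' @slot years Ordered integer vector of calendar years.
#' @slot seed Integer seed; all randomness in the generators derives from it.
#' @export
setClass("LandscapeSpec",
  representation(nRows = "integer", nCols = "integer",
                 classFractions = "numeric", conversionFraction = "numeric",
                 years = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "grid must have positive dimensions")
    cf <- object@classFractions
    wanted <- c("cropland", "forest", "shrubland", "grassland", "wetland", "nodata")
    if (!setequal(names(cf), wanted))
      msg <- c(msg, "classFractions must be named over the five classes plus nodata")
    if (abs(sum(cf) - 1) > 1e-9)
      msg <- c(msg, "classFractions must sum to 1 within 1e-9")
    if (any(cf < 0)) msg <- c(msg, "classFractions must be non-negative")
    if (object@conversionFraction < 0 || object@conversionFraction >= 1)
      msg <- c(msg, "conversionFraction must lie in [0, 1)")
    if (length(object@years) < 2L || is.unsorted(object@years, strictly = TRUE))
      msg <- c(msg, "years must be an increasing vector of length >= 2")
    if (length(msg)) msg else TRUE
  })

#' Construct a [LandscapeSpec-class]
#'
#' @param nRows,nCols Grid dimensions.
#' @param classFractions Named fractions over the five ecosystem classes and
#'   nodata; defaults emulate a grassland-dominated alpine mosaic
#'   (grassland 63.8 percent, forest 31.8 percent, small
#'   cropland/shrubland/wetland shares).
#' @param conversionFraction Proportion of vegetated pixels converted
#'   mid-series (default 0).
#' @param years Calendar years of the annual maps (default 1985:2020).
#' @param seed Integer seed.
#' @return A validated `LandscapeSpec`.
#' @examples
#' spec <- landscapeSpec(20, 20, conversionFraction = 0.1, seed = 1)
#' @export
landscapeSpec <- function(nRows, nCols,
                          classFractions = c(cropland = 0.018, forest = 0.3176,
                                             shrubland = 0.014, grassland = 0.6382,
                                             wetland = 0.0122, nodata = 0),
                          conversionFraction = 0,
                          years = 1985:2020,
                          seed = 1L) {
  new("LandscapeSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      classFractions = classFractions,
      conversionFraction = as.numeric(conversionFraction),
      years = as.integer(years), seed = as.integer(seed))
}

#' Generating-process parameters for the climate-vegetation cube
#'
#' Holds the true coefficients of the NDVI anomaly recursion
#' \deqn{N_t = \alpha T_t + \beta P_t + \gamma N_{t-1} + \varepsilon_t}
#' together with the monthly climatologies (offset + 12-month sinusoid) used
#' to embed the anomalies in physically scaled series, and an optional
#' temporal trend applied to the generating coefficients so that downstream
#' vulnerability series carry planted linear or piecewise signals.
#'
#' @slot alphaTrue,betaTrue,gammaTrue True coefficients; scalars (shared by
#'   all pixels) or per-pixel vectors.
#' @slot noiseSd Residual standard deviation of the anomaly recursion (> 0).
#' @slot seasonal Named list with elements `ndvi`, `temperature`,
#'   `precipitation`, each `c(mean =, amplitude =)`, plus `anomalySd` with
#'   per-variable anomaly scales used when mapping unit anomalies into
#'   physical units.
#' @slot trendSpec List describing a temporal modulation of the coefficients:
#'   `list(type = "none")`, `list(type = "linear", slope =)`, or
#'   `list(type = "piecewise", breakYear =, slope1 =, slope2 =)`. Slopes are
#'   per-year additive changes applied to alpha and beta; an optional
#'   `fraction` field (default 1) restricts the drift to a random subset of
#'   pixels, which matters because cross-pixel min-max normalization cancels
#'   a drift shared by every pixel.
#' @export
setClass("ProcessParams",
  representation(alphaTrue = "numeric", betaTrue = "numeric",
                 gammaTrue = "numeric", noiseSd = "numeric",
                 seasonal = "list", trendSpec = "list"),
  validity = function(object) {
    msg <- character()
    if (any(abs(object@gammaTrue) >= 1))
      msg <- c(msg, "|gammaTrue| must be < 1 (stationary AR(1) anomaly process)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
    need <- c("ndvi", "temperature", "precipitation")
    if (!all(need %in% names(object@seasonal)))
      msg <- c(msg, "seasonal must name ndvi, temperature and precipitation climatologies")
    tp <- object@trendSpec$type
    if (is.null(tp) || !tp %in% c("none", "linear", "piecewise"))
      msg <- c(msg, "trendSpec$type must be one of none/linear/piecewise")
    if (length(msg)) msg else TRUE
  })

#' Construct [ProcessParams-class]
#'
#' Defaults plant the reference recursion coefficients
#' `(alpha, beta, gamma) = (0.4, 0.3, 0.2)` at residual sd 0.1, with
#' climatologies typical of a cool alpine region: NDVI 0.45 +/- 0.25,
#' temperature 5 +/- 12 degC, precipitation 60 +/- 50 mm/month.
#'
#' @param alphaTrue,betaTrue,gammaTrue True recursion coefficients.
#' @param noiseSd Residual sd of the anomaly recursion.
#' @param seasonal Climatology list; see [ProcessParams-class].
#' @param trendSpec Temporal coefficient modulation; see [ProcessParams-class].
#' @return A validated `ProcessParams`.
#' @export
processParams <- function(alphaTrue = 0.4, betaTrue = 0.3, gammaTrue = 0.2,
                          noiseSd = 0.1,
                          seasonal = list(
                            ndvi = c(mean = 0.45, amplitude = 0.25),
                            temperature = c(mean = 5, amplitude = 12),
                            precipitation = c(mean = 60, amplitude = 50),
                            anomalySd = c(ndvi = 0.05, temperature = 1.5,
                                          precipitation = 15)),
                          trendSpec = list(type = "none")) {
  new("ProcessParams", alphaTrue = alphaTrue, betaTrue = betaTrue,
      gammaTrue = gammaTrue, noiseSd = noiseSd, seasonal = seasonal,
      trendSpec = trendSpec)
}

#' Driver-table specification
#'
#' Describes the 13 candidate driver features, the collinearity structure to
#' plant among them, and the per-feature response shapes that build the
#' synthetic target.
#'
#' @slot featureNames Character vector of feature names.
#' @slot featureRanges Named list of `c(min, max)` sampling ranges in natural
#'   units (mm, degC, kPa, SU/ha, ...).
#' @slot collinearPairs List of `list(a =, b =, r =)` entries; feature `b` is
#'   regenerated as an `r`-correlated copy of the (equal-weight, standardized)
#'   combination of the parent feature(s) named in `a`. With a single parent
#'   this is the classic correlated pair; with several parents the child's
#'   variance inflation exceeds any single parent's, so iterative VIF
#'   screening removes the child, not a parent.
#' @slot responseShapes Named list; each element is one of
#'   `list(shape = "flat")`, `list(shape = "linear", slope =)`,
#'   `list(shape = "step", threshold =, low =, high =)`,
#'   `list(shape = "v_shape", vertex =, slope =)`,
#'   `list(shape = "plateau", threshold =, slope =)` (linear decline up to the
#'   threshold, constant beyond it).
#' @slot noiseSd Target noise sd; if `NA`, set at run time to one tenth of
#'   the signal sd (signal-to-noise 10:1).
#' @export
setClass("DriverSpec",
  representation(featureNames = "character", featureRanges = "list",
                 collinearPairs = "list", responseShapes = "list",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(names(object@featureRanges) %in% object@featureNames))
      msg <- c(msg, "featureRanges must be named by featureNames")
    for (p in object@collinearPairs) {
      if (!all(c(p$a, p$b) %in% object@featureNames))
        msg <- c(msg, "collinear pair names features not in featureNames")
      if (abs(p$r) >= 1)
        msg <- c(msg, "collinear correlation must lie strictly inside (-1, 1)")
    }
    for (nm in names(object@responseShapes)) {
      rs <- object@responseShapes[[nm]]
      if (rs$shape %in% c("step", "plateau")) {
        rg <- object@featureRanges[[nm]]
        if (!is.null(rg) && (rs$threshold <= rg[1] || rs$threshold >= rg[2]))
          msg <- c(msg, sprintf("threshold for %s must lie strictly inside its range", nm))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a [DriverSpec-class]
#'
#' The default emulates the candidate set used for alpine-ecosystem
#' vulnerability work: 13 features (PRE, PET, AET, AI, VPD, RHU, SM, TEM,
#' TMX, TMN, SR, GI, NTL) on realistic ranges, with TEM, PET, AI, RHU and
#' NTL constructed as strongly collinear children of the remaining eight
#' (mean temperature from the extremes, potential evapotranspiration from
#' atmospheric demand and radiation, and so on), so that VIF screening at
#' cutoff 10 removes exactly those five. Planted nonlinear responses: a
#' soil-moisture plateau at 79 mm, a grazing step at 0.90 SU/ha, a VPD step
#' at 0.39 kPa and a precipitation plateau at 705 mm.
#'
#' @param featureNames,featureRanges,collinearPairs,responseShapes,noiseSd
#'   See [DriverSpec-class]; all have working defaults.
#' @return A validated `DriverSpec`.
#' @export
driverSpec <- function(featureNames = c("PRE", "PET", "AET", "AI", "VPD", "RHU",
                                        "SM", "TEM", "TMX", "TMN", "SR", "GI",
                                        "NTL"),
                       featureRanges = list(
                         PRE = c(475, 1080), PET = c(550, 950), AET = c(300, 700),
                         AI = c(0.4, 1.6), VPD = c(0.2, 0.55), RHU = c(50, 82),
                         SM = c(40, 120), TEM = c(-6, 10), TMX = c(2, 22),
                         TMN = c(-22, -2), SR = c(3000, 4100), GI = c(0, 2),
                         NTL = c(0, 5)),
                       collinearPairs = list(
                         list(a = c("TMX", "TMN", "SR"), b = "TEM", r = 0.96),
                         list(a = c("VPD", "TMX", "SR"), b = "PET", r = 0.96),
                         list(a = c("PRE", "TMN", "VPD"), b = "AI", r = 0.96),
                         list(a = c("SM", "PRE", "AET"), b = "RHU", r = 0.96),
                         list(a = c("GI", "AET", "SM"), b = "NTL", r = 0.96)),
                       responseShapes = list(
                         SM = list(shape = "plateau", threshold = 79, slope = -0.02),
                         GI = list(shape = "step", threshold = 0.90, low = 0.5, high = 0),
                         VPD = list(shape = "step", threshold = 0.39, low = 0.4, high = 0),
                         PRE = list(shape = "plateau", threshold = 705, slope = -0.001)),
                       noiseSd = NA_real_) {
  shapes <- lapply(featureNames, function(nm)
    responseShapes[[nm]] %||% list(shape = "flat"))
  names(shapes) <- featureNames
  new("DriverSpec", featureNames = featureNames, featureRanges = featureRanges,
      collinearPairs = collinearPairs, responseShapes = shapes,
      noiseSd = noiseSd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Aligned monthly climate-vegetation cube
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the three
#' co-registered monthly stacks as pixel-by-month assays `ndvi`,
#' `temperature` and `precipitation`. Rows are pixels (`rowData`: grid `row`,
#' `col`); columns are months (`colData`: `year`, `month`). Grid geometry
#' (rows, cols, cell size, origin, nodata sentinel) lives in
#' `metadata(x)$gridMeta`; generator ground truth, when present, in
#' `metadata(x)$truth`.
#'
#' @export
setClass("ClimateVegCube", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    need <- c("ndvi", "temperature", "precipitation")
    if (!all(need %in% assayNames(object)))
      msg <- c(msg, "assays must include ndvi, temperature, precipitation")
    cd <- colData(object)
    if (!all(c("year", "month") %in% colnames(cd)))
      msg <- c(msg, "colData must carry year and month")
    if (all(need %in% assayNames(object))) {
      pre <- assay(object, "precipitation")
      if (any(pre < 0, na.rm = TRUE))
        msg <- c(msg, "precipitation must be >= 0 wherever not nodata")
      nd <- assay(object, "ndvi")
      if (!all(vapply(need, function(a) identical(dim(assay(object, a)), dim(nd)),
                      logical(1))))
        msg <- c(msg, "all three stacks must share an identical shape")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a [ClimateVegCube-class]
#'
#' @param ndvi,temperature,precipitation Pixel-by-month matrices of identical
#'   shape. NDVI is unitless in `[-1, 1]`, temperature in degC, precipitation
#'   in mm (non-negative). `NA` encodes nodata.
#' @param years,months Integer vectors, one entry per column, giving the
#'   calendar time axis.
#' @param gridMeta List with at least `nRows` and `nCols`; optional
#'   `cellSize`, `xmin`, `ymax`, `nodata`.
#' @param truth Optional generator ground truth, stored in metadata.
#' @return A `ClimateVegCube`.
#' @export
climateVegCube <- function(ndvi, temperature, precipitation, years, months,
                           gridMeta, truth = NULL) {
  stopifnot(length(years) == ncol(ndvi), length(months) == ncol(ndvi))
  npix <- nrow(ndvi)
  if (is.null(gridMeta$cellSize)) gridMeta$cellSize <- 1
  rd <- DataFrame(row = rep(seq_len(gridMeta$nRows), times = gridMeta$nCols),
                  col = rep(seq_len(gridMeta$nCols), each = gridMeta$nRows))
  if (nrow(rd) != npix)
    stop("gridMeta dimensions inconsistent with assay rows")
  se <- SummarizedExperiment(
    assays = list(ndvi = ndvi, temperature = temperature,
                  precipitation = precipitation),
    rowData = rd,
    colData = DataFrame(year = as.integer(years), month = as.integer(months)))
  md <- list(gridMeta = gridMeta)
  if (!is.null(truth)) md$truth <- truth
  out <- new("ClimateVegCube", se)
  metadata(out) <- md
  out
}

#' Per-pixel annual vulnerability series
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with assays `EI`
#' (exposure), `SI` (sensitivity), `RI` (resilience), `VI` (vulnerability),
#' `tNorm` and `pNorm` (normalized window-mean hydrothermal state). Rows are
#' pixels, columns are window center years (`colData`: `centerYear`,
#' `startYear`, `endYear`).
#'
#' @export
setClass("VulnerabilitySeries", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    need <- c("EI", "SI", "RI", "VI", "tNorm", "pNorm")
    if (!all(need %in% assayNames(object)))
      msg <- c(msg, "assays must include EI, SI, RI, VI, tNorm, pNorm")
    if (!"centerYear" %in% colnames(colData(object)))
      msg <- c(msg, "colData must carry centerYear")
    if ("RI" %in% assayNames(object)) {
      ri <- assay(object, "RI")
      if (any(ri < -1e-9 | ri > 1 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "RI must lie in [0, 1] after coefficient normalization")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-pixel trend classification table
#'
#' Wraps an [S4Vectors::DFrame] with one row per pixel and the columns
#' `pixelId`, `cvPercent`, `cvBin`, `trendType`, `turningPattern`,
#' `turningYear`, `turningBin`, `modelChosen`, `slope1`, `slope2`,
#' `pLinear`, `pPiecewise`, `pPettitt`, `aicLinear`, `aicPiecewise`,
#' `aicPettitt`.
#'
#' @export
setClass("TrendClassification", contains = "DFrame",
  validity = function(object) {
    msg <- character()
    need <- c("pixelId", "cvPercent", "cvBin", "trendType", "turningPattern",
              "turningYear", "modelChosen")
    if (!all(need %in% colnames(object)))
      msg <- c(msg, paste("missing columns:",
                          paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (all(c("trendType", "turningYear") %in% colnames(object))) {
      ab <- !is.na(object$trendType) & object$trendType == "abrupt"
      if (any(ab & is.na(object$turningYear)))
        msg <- c(msg, "abrupt pixels must carry a turning year")
      if (any(!ab & !is.na(object$turningYear)))
        msg <- c(msg, "turning year present iff trend is abrupt")
    }
    if (length(msg)) msg else TRUE
  })

#' Driver-analysis results
#'
#' Bundles the outputs of the multicollinearity screen, the boosted-tree fit,
#' the SHAP attribution and the partial-dependence threshold readout.
#'
#' @slot retainedFeatures Features surviving VIF screening, in input order.
#' @slot vifReport Data frame of per-round VIF values.
#' @slot model The fitted `xgb.Booster` (or `NULL` for skipped classes).
#' @slot metrics Named list: `R2`, `MSE`, `RMSE`, `MAE` on the held-out split.
#' @slot importancePercent Named numeric, mean |SHAP| shares summing to 100.
#' @slot shapMatrix Sample-by-feature SHAP attribution matrix.
#' @slot baseValue Model expectation (SHAP base value).
#' @slot pdpCurves Named list of data frames `(grid, response)`.
#' @slot thresholds Named list of numeric threshold locations per feature.
#' @slot skipped Logical; `TRUE` when a stratum had too few samples.
#' @export
setClass("DriverAnalysis",
  representation(retainedFeatures = "character", vifReport = "data.frame",
                 model = "ANY", metrics = "list",
                 importancePercent = "numeric", shapMatrix = "matrix",
                 baseValue = "numeric", pdpCurves = "list",
                 thresholds = "list", skipped = "logical"),
  prototype(skipped = FALSE),
  validity = function(object) {
    msg <- character()
    if (!object@skipped && length(object@importancePercent) &&
        abs(sum(object@importancePercent) - 100) > 1e-6)
      msg <- c(msg, "importancePercent must sum to 100 within 1e-6")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ClimateVegCube", function(object) {
  gm <- metadata(object)$gridMeta
  cd <- colData(object)
  cat("ClimateVegCube:", gm$nRows, "x", gm$nCols, "pixels,",
      ncol(object), "months (", min(cd$year), "-", max(cd$year), ")\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(metadata(object)$truth))
    cat("  generator ground truth attached\n")
})

setMethod("show", "VulnerabilitySeries", function(object) {
  cd <- colData(object)
  cat("VulnerabilitySeries:", nrow(object), "pixels,", ncol(object),
      "windows (center years", min(cd$centerYear), "-", max(cd$centerYear), ")\n")
  vi <- assay(object, "VI")
  cat(sprintf("  VI: %d valid pixel-windows, median %.3f\n",
              sum(!is.na(vi)), stats::median(vi, na.rm = TRUE)))
})

setMethod("show", "TrendClassification", function(object) {
  cat("TrendClassification:", nrow(object), "pixels\n")
  tt <- table(object$trendType, useNA = "ifany")
  for (nm in names(tt)) cat(sprintf("  %-16s %d\n", nm, tt[[nm]]))
})

setMethod("show", "DriverAnalysis", function(object) {
  if (object@skipped) {
    cat("DriverAnalysis: skipped (insufficient samples)\n")
    return(invisible(NULL))
  }
  cat("DriverAnalysis:", length(object@retainedFeatures), "retained features\n")
  m <- object@metrics
  cat(sprintf("  held-out R2 %.3f, RMSE %.4f, MAE %.4f\n",
              m$R2, m$RMSE, m$MAE))
  imp <- sort(object@importancePercent, decreasing = TRUE)
  top <- utils::head(imp, 4)
  cat("  top importance:",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Accessors for the analysis containers
#'
#' `vulnerability`, `exposure`, `sensitivity` and `resilience` return the
#' pixel-by-year VI/EI/SI/RI matrices of a [VulnerabilitySeries-class];
#' `retainedFeatures`, `importancePercent`, `shapValues`, `pdpCurves`,
#' `modelMetrics` and `thresholds` unpack a [DriverAnalysis-class].
#'
#' @param x The container.
#' @return Matrix, vector or list as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vulnerability", function(x) standardGeneric("vulnerability"))
#' @rdname accessors
#' @export
setMethod("vulnerability", "VulnerabilitySeries", function(x) assay(x, "VI"))

#' @rdname accessors
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))
#' @rdname accessors
#' @export
setMethod("exposure", "VulnerabilitySeries", function(x) assay(x, "EI"))

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setMethod("sensitivity", "VulnerabilitySeries", function(x) assay(x, "SI"))

#' @rdname accessors
#' @export
setGeneric("resilience", function(x) standardGeneric("resilience"))
#' @rdname accessors
#' @export
setMethod("resilience", "VulnerabilitySeries", function(x) assay(x, "RI"))

#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))
#' @rdname accessors
#' @export
setMethod("retainedFeatures", "DriverAnalysis", function(x) x@retainedFeatures)

#' @rdname accessors
#' @export
setGeneric("importancePercent", function(x) standardGeneric("importancePercent"))
#' @rdname accessors
#' @export
setMethod("importancePercent", "DriverAnalysis", function(x) x@importancePercent)

#' @rdname accessors
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))
#' @rdname accessors
#' @export
setMethod("shapValues", "DriverAnalysis", function(x)
  list(shap = x@shapMatrix, baseValue = x@baseValue))

#' @rdname accessors
#' @export
setGeneric("pdpCurves", function(x) standardGeneric("pdpCurves"))
#' @rdname accessors
#' @export
setMethod("pdpCurves", "DriverAnalysis", function(x) x@pdpCurves)

#' @rdname accessors
#' @export
setGeneric("modelMetrics", function(x) standardGeneric("modelMetrics"))
#' @rdname accessors
#' @export
setMethod("modelMetrics", "DriverAnalysis", function(x) x@metrics)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "DriverAnalysis", function(x) x@thresholds)
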
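## Pipeline orchestration and area-percentage summaries.

#' Assemble a pipeline configuration
#'
#' Bundles the synthetic-landscape, generating-process and driver
#' specifications with the window, significance, binning and
#' driver-analysis settings used by [runPipeline()].
#'
#' @param landscape A [LandscapeSpec-class].
#' @param process A [ProcessParams-class].
#' @param driver A [DriverSpec-class] providing the driver-feature ranges
#'   and collinearity structure for the pixel-year driver table.
#' @param windowLength,windowStep Sliding-window geometry (defaults 5, 1).
#' @param significance Significance level for all trend tests, in (0, 1).
#' @param cvBinEdges CV bin boundaries in percent (default `c(20, 30)`).
#' @param turningBinEdges Turning-year interval edges
#'   (default `seq(1990, 2015, 5)`); must be strictly increasing.
#' @param minSegment Minimum piecewise segment length (default 5 years).
#' @param boundaryYears Turning-point boundary-exclusion distance (default 5).
#' @param driverGrid Hyperparameter grid for the pipeline's boosted fits; the
#'   default is a deliberately small two-configuration grid so a full run
#'   stays interactive. Pass [defaultXgbGrid()] for the full search.
#' @param splitFraction,vifCutoff,nPdp,pdpMode,minClassSamples Driver-stage
#'   settings; see [analyzeDrivers()] and [perEcosystemAnalysis()].
#' @param normalizationScope Passed to [buildViSeries()].
#' @param outputDir Directory for artifacts, or `NULL` to skip writing.
#' @param seed Integer master seed for the driver-table assembly and model
#'   fits (the generators carry their own seed in `landscape`).
#' @return Validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(landscape, process = processParams(),
                           driver = driverSpec(),
                           windowLength = 5L, windowStep = 1L,
                           significance = 0.05, cvBinEdges = c(20, 30),
                           turningBinEdges = seq(1990, 2015, 5),
                           minSegment = 5L, boundaryYears = 5L,
                           driverGrid = expand.grid(nrounds = 150L,
                                                    max_depth = c(3L, 5L),
                                                    eta = 0.1, subsample = 1.0),
                           splitFraction = 0.8, vifCutoff = 10, nPdp = 4L,
                           pdpMode = "at_means", minClassSamples = 500L,
                           normalizationScope = "window",
                           outputDir = NULL, seed = 1L) {
  stopifnot(is(landscape, "LandscapeSpec"), is(process, "ProcessParams"),
            is(driver, "DriverSpec"))
  if (significance <= 0 || significance >= 1)
    stop("significance level must lie in (0, 1)")
  if (is.unsorted(cvBinEdges, strictly = TRUE) ||
      is.unsorted(turningBinEdges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  structure(list(landscape = landscape, process = process, driver = driver,
                 windowLength = windowLength, windowStep = windowStep,
                 significance = significance, cvBinEdges = cvBinEdges,
                 turningBinEdges = turningBinEdges, minSegment = minSegment,
                 boundaryYears = boundaryYears, driverGrid = driverGrid,
                 splitFraction = splitFraction, vifCutoff = vifCutoff,
                 nPdp = nPdp, pdpMode = pdpMode,
                 minClassSamples = minClassSamples,
                 normalizationScope = normalizationScope,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Area-percentage summary tables
#'
#' Cross-tabulates the per-pixel classification by CV bin, trend type,
#' turning pattern and turning-year bin, overall and stratified by stable
#' ecosystem class. Percentages are reported against two denominators: the
#' total valid classified area (`percentTotal`, the primary convention, so
#' class breakdowns are shares of the whole region) and the stratum's own
#' area (`percentWithin`). Within each stratum and variable the levels close
#' to 100% of the stratum.
#'
#' @param classifications A [TrendClassification-class] (or data frame).
#' @param mask Stable-pixel mask from [stablePixelMask()], or `NULL` for an
#'   unstratified summary. Pixels are matched to rows by column-major order.
#' @return Data frame with `stratum`, `variable`, `level`, `count`,
#'   `percentTotal`, `percentWithin`.
#' @export
summarizeAreas <- function(classifications, mask = NULL) {
  df <- as.data.frame(classifications)
  valid <- !is.na(df$trendType)
  if (!is.null(mask)) {
    m <- as.integer(mask)
    if (length(m) != nrow(df)) stop("mask geometry does not match classification")
    cls <- rep(NA_character_, length(m))
    stable <- m > 0L
    cls[stable] <- names(LC_CODES)[match(m[stable], LC_CODES)]
    df$class <- cls
  } else df$class <- NA_character_

  df <- df[valid, , drop = FALSE]
  total <- nrow(df)
  if (!total) stop("no valid classified pixels to summarize")

  fill <- function(x, lev) factor(ifelse(is.na(x), "none", x),
                                  levels = unique(c(lev, "none")))
  vars <- list(
    cvBin = fill(df$cvBin, c("<20", "20-30", ">30")),
    trendType = fill(df$trendType,
                     c("no_trend", "linear_increase", "linear_decrease", "abrupt")),
    turningPattern = fill(df$turningPattern, c("I_D", "D_I")),
    turningBin = fill(df$turningBin, unique(df$turningBin[!is.na(df$turningBin)])))

  strata <- c("all", sort(unique(df$class[!is.na(df$class)])))
  out <- list()
  for (st in strata) {
    inSt <- if (st == "all") rep(TRUE, total) else !is.na(df$class) & df$class == st
    nSt <- sum(inSt)
    for (v in names(vars)) {
      tab <- table(vars[[v]][inSt])
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, variable = v, level = names(tab),
        count = as.integer(tab),
        percentTotal = 100 * as.integer(tab) / total,
        percentWithin = if (nSt > 0) 100 * as.integer(tab) / nSt else NA_real_,
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# Pixel-year driver table paired with the pipeline's VI: features drawn per
# pixel-year from the DriverSpec ranges (with its collinearity structure),
# target = that pixel-year's VI.
assembleDriverTable <- function(vi, mask, spec, seed) {
  viM <- vulnerability(vi)
  ok <- which(!is.na(viM))
  n <- length(ok)
  withSeed(seed, {
    X <- vapply(spec@featureNames, function(nm) {
      rg <- spec@featureRanges[[nm]]
      runif(n, rg[1], rg[2])
    }, numeric(n))
    colnames(X) <- spec@featureNames
    X <- plantCollinearity(X, spec@collinearPairs, spec@featureRanges)
  })
  pix <- row(viM)[ok]
  m <- as.integer(mask)
  cls <- rep(NA_character_, length(m))
  stable <- m > 0L
  cls[stable] <- names(LC_CODES)[match(m[stable], LC_CODES)]
  list(features = as.data.frame(X), target = as.numeric(viM[ok]),
       pixel = pix, year = colData(vi)$centerYear[col(viM)[ok]],
       class = cls[pix])
}

#' Run the full pipeline on a synthetic landscape
#'
#' Executes simulate, preprocess, vulnerability, trend,
#' stratify and drivers in order: generates the land-cover stack and
#' climate-vegetation cube, derives the stable-pixel mask, builds the VI
#' series, classifies every pixel's trend, summarizes area percentages
#' overall and per ecosystem, and runs the driver chain on the pooled
#' pixel-year table and per ecosystem class. All stages are seeded, so a
#' rerun with an identical configuration is bit-identical.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @param verbose Log stage progress and record counts to stderr
#'   (default `TRUE`).
#' @return List: `landcover`, `cube`, `mask`, `vi`, `classification`,
#'   `areas`, `turningTable`, `drivers` (with `$overall` and `$perClass`),
#'   `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[EcoVuln] ", ...)

  say("simulate: land cover (", config$landscape@nRows, "x",
      config$landscape@nCols, ")")
  lc <- generateLandcover(config$landscape)
  say("simulate: climate-vegetation cube")
  cube <- generateClimateVeg(config$landscape, config$process)

  say("preprocess: stable-pixel mask over ", dim(lc$maps)[3], " years")
  mask <- stablePixelMask(lc$maps)

  say("vulnerability: sliding windows")
  vi <- buildViSeries(cube, windowLength = config$windowLength,
                      windowStep = config$windowStep,
                      normalizationScope = config$normalizationScope)
  say("vulnerability: ", sum(!is.na(vulnerability(vi))), " valid pixel-windows")

  say("trend: classifying ", nrow(vi), " pixels")
  cls <- classifyTrends(vi, alpha = config$significance,
                        minSegment = config$minSegment,
                        boundaryYears = config$boundaryYears,
                        binEdges = config$turningBinEdges)

  say("report: area summaries")
  areas <- summarizeAreas(cls, mask)
  turning <- binTurningYears(cls, config$turningBinEdges)

  say("drivers: pooled pixel-year table")
  tab <- assembleDriverTable(vi, mask, config$driver, config$seed)
  overall <- analyzeDrivers(tab$features, tab$target,
                            vifCutoff = config$vifCutoff,
                            splitFraction = config$splitFraction,
                            grid = config$driverGrid, seed = config$seed,
                            nPdp = config$nPdp, pdpMode = config$pdpMode)
  perClass <- list()
  for (cl in LC_CLASSES) {
    rows <- which(!is.na(tab$class) & tab$class == cl)
    if (length(rows) < config$minClassSamples) {
      say("drivers: class ", cl, " skipped (", length(rows), " samples)")
      perClass[[cl]] <- new("DriverAnalysis",
                            retainedFeatures = character(0),
                            vifReport = data.frame(), model = NULL,
                            metrics = list(), importancePercent = numeric(0),
                            shapMatrix = matrix(numeric(0), 0, 0),
                            baseValue = NA_real_, pdpCurves = list(),
                            thresholds = list(), skipped = TRUE)
      next
    }
    say("drivers: class ", cl, " (", length(rows), " pixel-years)")
    perClass[[cl]] <- analyzeDrivers(tab$features[rows, , drop = FALSE],
                                     tab$target[rows],
                                     vifCutoff = config$vifCutoff,
                                     splitFraction = config$splitFraction,
                                     grid = config$driverGrid,
                                     seed = config$seed, nPdp = config$nPdp,
                                     pdpMode = config$pdpMode)
  }

  manifest <- list(
    seed = config$seed,
    landscapeSeed = config$landscape@seed,
    grid = c(config$landscape@nRows, config$landscape@nCols),
    years = range(config$landscape@years),
    windowLength = config$windowLength,
    significance = config$significance,
    nValidPixels = sum(!is.na(cls$trendType)),
    versions = list(R = R.version.string,
                    EcoVuln = as.character(utils::packageVersion("EcoVuln")),
                    xgboost = as.character(utils::packageVersion("xgboost"))))

  result <- list(landcover = lc, cube = cube, mask = mask, vi = vi,
                 classification = cls, areas = areas, turningTable = turning,
                 drivers = list(overall = overall, perClass = perClass),
                 manifest = manifest)
  if (!is.null(config$outputDir)) writeArtifacts(result, config$outputDir)
  result
}

# Tidy CSV/JSON artifacts for a pipeline run.
writeArtifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  viM <- vulnerability(result$vi)
  cd <- colData(result$vi)
  tidy <- data.frame(pixelId = as.integer(row(viM)),
                     year = cd$centerYear[as.integer(col(viM))],
                     EI = as.numeric(exposure(result$vi)),
                     SI = as.numeric(sensitivity(result$vi)),
                     RI = as.numeric(resilience(result$vi)),
                     VI = as.numeric(viM))
  utils::write.csv(tidy, file.path(dir, "vi_series.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$classification),
                   file.path(dir, "trend_classification.csv"), row.names = FALSE)
  utils::write.csv(result$areas, file.path(dir, "area_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$turningTable, file.path(dir, "turning_years.csv"),
                   row.names = FALSE)
  ov <- result$drivers$overall
  utils::write.csv(data.frame(feature = names(importancePercent(ov)),
                              importancePercent = importancePercent(ov)),
                   file.path(dir, "driver_importance.csv"), row.names = FALSE)
  jsonlite::write_json(list(metrics = modelMetrics(ov),
                            thresholds = thresholds(ov)),
                       file.path(dir, "driver_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
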
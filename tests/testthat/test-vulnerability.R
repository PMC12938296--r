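test_that("window enumeration reproduces the 36-window layout", {
  w <- enumerateWindows(1983, 2022)
  expect_equal(nrow(w), 36)
  expect_equal(w$startYear[1], 1983); expect_equal(w$endYear[1], 1987)
  expect_equal(w$startYear[36], 2018); expect_equal(w$endYear[36], 2022)
  expect_equal(w$centerYear, 1985:2020)

  expect_equal(nrow(enumerateWindows(2000, 2004)), 1)
  expect_error(enumerateWindows(2000, 2003), "shorter")
})

test_that("window model fit is OLS of NDVI on temperature, precipitation and lag", {
  cube <- tinyCube(6, 6, years = 1983:1987, seed = 3,
                   params = processParams(noiseSd = 0.05))
  tr <- cubeTruth(cube)
  for (p in 1:10) {
    f <- fitWindowModel(tr$anomalies$ndvi[p, ], tr$anomalies$temperature[p, ],
                        tr$anomalies$precipitation[p, ])
    # within 3 standard errors of truth (se ~ noiseSd / sqrt(n))
    se <- f$residualSd / sqrt(f$nObs)
    expect_lt(abs(f$alpha - 0.4), 3 * se * 1.5)
    expect_lt(abs(f$beta - 0.3), 3 * se * 1.5)
  }

  # perfect predictor: NDVI identical to temperature
  set.seed(4)
  nd <- rnorm(60); pre <- rnorm(60)
  f <- fitWindowModel(nd, nd, pre)
  expect_equal(f$alpha, 1, tolerance = 1e-8)
  expect_equal(f$beta, 0, tolerance = 1e-8)
  expect_equal(f$gamma, 0, tolerance = 1e-8)

  # OLS normal equations: residuals orthogonal to every regressor
  set.seed(5)
  nd <- rnorm(60); tt <- rnorm(60); pp <- rnorm(60)
  f <- fitWindowModel(nd, tt, pp)
  res <- nd[-1] - (f$intercept + f$alpha * tt[-1] + f$beta * pp[-1] +
                     f$gamma * nd[-60])
  expect_lt(abs(sum(res * tt[-1])), 1e-8)
  expect_lt(abs(sum(res * pp[-1])), 1e-8)
  expect_lt(abs(sum(res * nd[-60])), 1e-8)
  expect_equal(f$nObs, 59L)

  # rank deficiency is flagged, not raised
  expect_false(fitWindowModel(rep(1, 60), rep(2, 60), rep(3, 60))$valid)
  expect_false(fitWindowModel(c(NA, rnorm(59)), rnorm(60), rnorm(60))$valid)
})

test_that("coefficient normalization is rank-preserving min-max per channel", {
  co <- cbind(alpha = c(-0.2, 0.3, 0.8), beta = c(0, 1, 2), gamma = c(0.5, 0.2, 0.9))
  nm <- normalizeCoefficients(co)
  expect_equal(unname(nm[, "alpha"]), c(0, 0.5, 1))

  expect_warning(nm1 <- minMaxScale(c(0.4)), "degenerate")
  expect_equal(nm1, 0.5)

  set.seed(20)
  co <- cbind(alpha = rnorm(100), beta = rnorm(100), gamma = rnorm(100))
  nm <- normalizeCoefficients(co)
  expect_true(all(nm >= 0 & nm <= 1))
  for (ch in colnames(co))
    expect_equal(cor(nm[, ch], co[, ch], method = "spearman"), 1)
})

test_that("hydrothermal norms map window means onto [0, 1] across pixels", {
  tw <- rbind(rep(0, 12), rep(10, 12))
  pw <- rbind(rep(30, 12), rep(80, 12))
  hn <- computeHydrothermalNorms(tw, pw)
  expect_equal(hn$tNorm, c(0, 1))
  expect_equal(hn$pNorm, c(0, 1))

  expect_warning(hn0 <- computeHydrothermalNorms(matrix(5, 3, 12),
                                                 matrix(runif(36), 3, 12)),
                 "degenerate")
  expect_equal(hn0$tNorm, rep(0.5, 3))

  set.seed(21)
  tw <- matrix(rnorm(50 * 12), 50)
  hn <- computeHydrothermalNorms(tw, abs(tw))
  expect_equal(cor(hn$tNorm, rowMeans(tw), method = "spearman"), 1)
})

test_that("index algebra matches its defining formulas at the corners", {
  z <- computeIndices(0, 0, 0.5, 0.5, 0.5)
  expect_equal(unlist(z[c("EI", "SI", "VI")]), c(EI = 0, SI = 0, VI = 0))

  # gamma_norm = 1: no resilience buffering, VI = EI * SI
  z <- computeIndices(0.5, 0.5, 1, 1, 1)
  expect_equal(z$RI, 0)
  expect_equal(z$VI, z$EI * z$SI)

  z <- computeIndices(1, 1, 0, 1, 1)
  expect_equal(unlist(z), c(EI = 2, SI = 2, RI = 1, VI = 2))

  expect_error(computeIndices(1.2, 0, 0, 0, 0), "\\[0, 1\\]")
})

test_that("the VI series spans the center years and respects nodata", {
  spec <- landscapeSpec(4, 4, years = 1983:2022, seed = 9,
                        classFractions = c(cropland = 0, forest = 0.3,
                                           shrubland = 0, grassland = 0.6,
                                           wetland = 0, nodata = 0.1))
  cube <- generateClimateVeg(spec, processParams())
  vi <- buildViSeries(cube)
  expect_s4_class(vi, "VulnerabilitySeries")
  expect_equal(SummarizedExperiment::colData(vi)$centerYear, 1985:2020)
  expect_equal(ncol(vi), 36)

  viM <- vulnerability(vi)
  expect_true(all(viM >= 0 & viM <= 4, na.rm = TRUE))

  # all-nodata pixels emit all-nodata VI
  nd <- which(is.na(SummarizedExperiment::assay(cube, "ndvi")[, 1]))
  expect_gt(length(nd), 0)
  expect_true(all(is.na(viM[nd, ])))
})

test_that("VI is invariant to positive rescaling of the raw inputs", {
  cube <- tinyCube(4, 4, years = 1983:1992, seed = 13)
  vi1 <- vulnerability(buildViSeries(cube))
  scaled <- climateVegCube(
    SummarizedExperiment::assay(cube, "ndvi") * 3.7,
    SummarizedExperiment::assay(cube, "temperature") * 1.8,
    SummarizedExperiment::assay(cube, "precipitation") * 0.25,
    years = SummarizedExperiment::colData(cube)$year,
    months = SummarizedExperiment::colData(cube)$month,
    gridMeta = S4Vectors::metadata(cube)$gridMeta)
  vi2 <- vulnerability(buildViSeries(scaled))
  expect_equal(vi1, vi2, tolerance = 1e-9)
})
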
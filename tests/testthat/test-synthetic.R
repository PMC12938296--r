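test_that("land-cover generator honors conversion fraction and determinism", {
  # no conversion: every pixel constant
  lc0 <- generateLandcover(landscapeSpec(10, 10, conversionFraction = 0, seed = 3))
  m0 <- matrix(lc0$maps, nrow = 100)
  expect_true(all(m0 == m0[, 1]))

  # independent per-pixel equality scan recovers exactly 10% converted
  spec <- landscapeSpec(20, 20, conversionFraction = 0.1, seed = 1)
  lc <- generateLandcover(spec)
  m <- matrix(lc$maps, nrow = 400)
  changed <- which(rowSums(m != m[, 1]) > 0)
  nVeg <- sum(m[, 1] != landcoverCodes()[["nodata"]])
  expect_equal(length(changed), round(0.1 * nVeg))
  expect_setequal(changed, lc$truth$converted)

  # bit-identical rerun
  expect_identical(lc$maps, generateLandcover(spec)$maps)
})

test_that("land-cover generator rejects degenerate specs", {
  expect_error(landscapeSpec(0, 5, seed = 1), "positive dimensions")
  expect_error(landscapeSpec(5, 5, conversionFraction = 1, seed = 1), "\\[0, 1\\)")
  expect_error(landscapeSpec(5, 5, seed = 1,
                             classFractions = c(cropland = 0.5, forest = 0.6,
                                                shrubland = 0, grassland = 0,
                                                wetland = 0, nodata = 0)),
               "sum to 1")
})

test_that("climate-veg cube follows the anomaly recursion", {
  # null process: NDVI anomalies are i.i.d., lag-1 autocorrelation near 0
  cube0 <- tinyCube(5, 5, years = 1983:1992, seed = 7,
                    params = processParams(alphaTrue = 0, betaTrue = 0,
                                           gammaTrue = 0))
  N <- cubeTruth(cube0)$anomalies$ndvi
  n <- ncol(N)
  ac1 <- apply(N, 1, function(x) cor(x[-1], x[-n]))
  expect_true(all(abs(ac1) < 3 / sqrt(n)))

  # OLS re-fit of the recursion recovers the coefficients
  cube <- tinyCube(10, 10, years = 1983:1987, seed = 11)
  tr <- cubeTruth(cube)
  est <- t(sapply(1:100, function(p) {
    f <- fitWindowModel(tr$anomalies$ndvi[p, ], tr$anomalies$temperature[p, ],
                        tr$anomalies$precipitation[p, ])
    c(f$alpha, f$beta, f$gamma)
  }))
  expect_lt(max(abs(colMeans(est) - c(0.4, 0.3, 0.2))), 0.03)

  # noise-free limit: the recursion is reproduced to round-off
  cubeE <- tinyCube(3, 3, years = 1983:1987, seed = 5,
                    params = processParams(noiseSd = 1e-12))
  trE <- cubeTruth(cubeE)
  N <- trE$anomalies$ndvi; Tt <- trE$anomalies$temperature
  P <- trE$anomalies$precipitation
  recon <- 0.4 * Tt[, -1] + 0.3 * P[, -1] + 0.2 * N[, -ncol(N)]
  expect_lt(max(abs(N[, -1] - recon)), 1e-9)

  expect_error(generateClimateVeg(landscapeSpec(3, 3, years = 1983:1986, seed = 1),
                                  processParams()), "60 months")
  expect_error(processParams(gammaTrue = 1), "stationary")
})

test_that("planted VI series carry their stated signal", {
  # constant when noise-free with no trend
  g0 <- generateViSeries(list(type = "none"), 12, 0, seed = 1)
  expect_true(all(g0$series == g0$series[1]))

  # noise-free V-shape has its minimum at the planted break
  gV <- generateViSeries(list(type = "piecewise", breakYear = 2010,
                              slope1 = -0.01, slope2 = 0.01), 36, 0, seed = 1)
  expect_equal(unname(gV$years[which.min(gV$series)]), 2010)

  # OLS slope within 2 standard errors of the planted slope
  gL <- generateViSeries(list(type = "linear", slope = 0.02), 36, 0.05, seed = 7)
  f <- summary(lm(gL$series ~ gL$years))$coefficients
  expect_lt(abs(f[2, 1] - 0.02) / f[2, 2], 2)

  expect_error(generateViSeries(list(type = "none"), 10, 0, seed = 1), ">= 11")
  expect_error(generateViSeries(list(type = "piecewise", breakYear = 1986,
                                     slope1 = -1, slope2 = 1), 36, 0, seed = 1),
               "too close")
})

test_that("driver tables plant collinearity and response shapes", {
  ds <- driverSpec(collinearPairs = list(list(a = "TMX", b = "TEM", r = 0.999)),
                   responseShapes = list(
                     SM = list(shape = "step", threshold = 79, low = 1, high = 0)),
                   noiseSd = 0.1)
  dt <- generateDriverTable(ds, 2000, seed = 2)
  expect_gte(cor(dt$features$TMX, dt$features$TEM), 0.99)

  # two-group means across the step threshold recover the planted drop
  lo <- mean(dt$target[dt$features$SM < 79])
  hi <- mean(dt$target[dt$features$SM >= 79])
  expect_lt(abs((lo - hi) - 1.0), 0.1)

  # determinism and sidecar truth
  dt2 <- generateDriverTable(ds, 2000, seed = 2)
  expect_identical(dt$features, dt2$features)
  expect_identical(dt$target, dt2$target)
  expect_equal(dt$truth$noiseSd, 0.1)

  expect_error(driverSpec(collinearPairs = list(list(a = "TMX", b = "TEM", r = 1))),
               "strictly inside")
  expect_error(generateDriverTable(ds, 100, seed = 1), ">= 500")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateLandcover(landscapeSpec(5, 5, seed = 1)))
  invisible(generateViSeries(list(type = "none"), 12, 0.1, seed = 2))
  expect_identical(.Random.seed, before)
})
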
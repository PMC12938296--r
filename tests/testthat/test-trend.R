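test_that("coefficient of variation matches hand and oracle computations", {
  cv <- coefficientOfVariation(rep(2.5, 10))
  expect_equal(cv$cvPercent, 0)
  expect_equal(cv$cvBin, "<20")

  # mean 1.5, sample sd 1 -> 66.7%
  cv <- coefficientOfVariation(c(1, 1, 1, 3))
  expect_equal(cv$cvPercent, 100 / 1.5, tolerance = 1e-12)
  expect_equal(cv$cvBin, ">30")

  set.seed(41)
  x <- abs(rnorm(36)) + 1
  expect_equal(coefficientOfVariation(x)$cvPercent, 100 * sd(x) / mean(x))

  expect_false(coefficientOfVariation(rep(0, 10))$valid)
})

test_that("linear fit reports slope test and least-squares AIC", {
  yrs <- 1985:2020
  f <- fitLinear(0.01 * yrs + 0.3, yrs)
  expect_equal(f$slope, 0.01, tolerance = 1e-10)
  expect_lt(f$p, 1e-12)

  # AIC recomputed independently from lm residuals
  set.seed(42)
  y <- rnorm(36)
  f <- fitLinear(y, yrs)
  rss <- sum(resid(lm(y ~ yrs))^2)
  expect_equal(f$aic, 36 * log(rss / 36) + 2 * 3, tolerance = 1e-10)

  # type-I calibration: ~5% under white noise
  set.seed(43)
  rej <- mean(replicate(1000, fitLinear(rnorm(36), yrs)$p < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)

  z <- fitLinear(rep(1, 10))
  expect_equal(z$slope, 0); expect_equal(z$p, 1)
})

test_that("piecewise search finds the RSS-minimizing admissible break", {
  g <- generateViSeries(list(type = "piecewise", breakYear = 2004,
                             slope1 = -0.02, slope2 = 0.02), 36, 0, seed = 1)
  pw <- fitPiecewise(g$series, g$years)
  expect_equal(pw$breakYear, 2004)  # index 20 of 36, recovered exactly
  expect_equal(pw$slopes, c(-0.02, 0.02), tolerance = 1e-8)

  # brute-force oracle: no admissible candidate beats the chosen RSS
  set.seed(44)
  y <- rnorm(36); yrs <- 1985:2020
  pw <- fitPiecewise(y, yrs, minSegment = 5)
  for (bi in 5:32) {
    hin <- pmax(yrs - yrs[bi], 0)
    rssB <- sum(resid(lm(y ~ yrs + hin))^2)
    expect_gte(rssB, pw$rss - 1e-9)
  }

  # noisy planted break recovered within +-2 years in >= 90% of reps
  hits <- sum(sapply(1:50, function(s) {
    g <- generateViSeries(list(type = "piecewise", breakYear = 2004,
                               slope1 = -0.02, slope2 = 0.02), 36, 0.038, seed = s)
    abs(fitPiecewise(g$series, g$years)$breakYear - 2004) <= 2
  }))
  expect_gte(hits, 45)

  expect_false(fitPiecewise(rnorm(10), 1:10, minSegment = 5)$available)
})

test_that("Pettitt statistic equals its brute-force definition", {
  set.seed(45)
  for (i in 1:20) {
    n <- sample(8:12, 1)
    x <- if (i %% 3 == 0) sample(rep(1:4, 3), n) else rnorm(n)  # ties included
    pt <- pettittTest(x)
    U <- sapply(1:(n - 1), function(t)
      sum(outer(x[1:t], x[(t + 1):n], function(a, b) sign(b - a))))
    expect_equal(pt$u, as.numeric(U))
    expect_equal(pt$k, max(abs(U)))
    expect_equal(pt$changeIndex, which.max(abs(U)))
    expect_equal(pt$p, min(1, 2 * exp(-6 * max(abs(U))^2 / (n^3 + n^2))))
  }

  # constant series: all U zero, p = 1
  pt <- pettittTest(rep(1, 10))
  expect_true(all(pt$u == 0))
  expect_equal(pt$p, 1)
})

test_that("every valid series maps to exactly one trend class", {
  types <- c("no_trend", "linear_increase", "linear_decrease", "abrupt")
  set.seed(46)
  for (i in 1:30) {
    y <- switch(1 + i %% 3,
                rnorm(36, 1, 0.1),
                1 + 0.02 * (1:36) + rnorm(36, 0, 0.2),
                1 + c(seq(0.3, 0, length.out = 18),
                      seq(0, 0.3, length.out = 18)) + rnorm(36, 0, 0.05))
    cl <- classifyTrend(y, 1985:2020)
    expect_true(cl$trendType %in% types)
    expect_identical(cl$trendType == "abrupt", !is.na(cl$turningYear))
  }

  # invalid input classified nodata, not an error
  expect_true(is.na(classifyTrend(c(NA, rnorm(35)), 1985:2020)$trendType))
})

test_that("abrupt patterns carry the segment-slope signs", {
  gDI <- generateViSeries(list(type = "piecewise", breakYear = 2005,
                               slope1 = -0.02, slope2 = 0.02), 36, 0.02, seed = 3)
  cl <- classifyTrend(gDI$series, gDI$years)
  expect_equal(cl$trendType, "abrupt")
  expect_equal(cl$turningPattern, "D_I")
  expect_lt(cl$slope1, 0); expect_gt(cl$slope2, 0)

  gID <- generateViSeries(list(type = "piecewise", breakYear = 2005,
                               slope1 = 0.02, slope2 = -0.02), 36, 0.02, seed = 3)
  cl <- classifyTrend(gID$series, gID$years)
  expect_equal(cl$turningPattern, "I_D")
})

test_that("turning-year binning equals a brute-force histogram and closes", {
  empty <- binTurningYears(data.frame(trendType = "no_trend", turningYear = NA))
  expect_equal(nrow(empty), 0)

  df <- data.frame(trendType = c(rep("abrupt", 3), "no_trend"),
                   turningYear = c(2011, 2012, 2014, NA))
  tb <- binTurningYears(df)
  expect_equal(tb$count[tb$bin == "2010-2015"], 3)
  expect_equal(sum(tb$count), 3)

  set.seed(47)
  ty <- sample(1991:2014, 200, replace = TRUE)
  df <- data.frame(trendType = "abrupt", turningYear = ty)
  tb <- binTurningYears(df)
  edges <- seq(1990, 2015, 5)
  oracle <- table(cut(ty, edges, right = FALSE, include.lowest = TRUE))
  expect_equal(tb$count, as.integer(oracle))
  expect_equal(sum(tb$areaPercent), 100, tolerance = 1e-9)
})

test_that("classifyTrends maps a matrix of pixels and labels bins", {
  set.seed(48)
  m <- rbind(rep(1, 36) + rnorm(36, 0, 0.05),
             1 + 0.02 * (1:36) + rnorm(36, 0, 0.05))
  cls <- classifyTrends(m, years = 1985:2020)
  expect_s4_class(cls, "TrendClassification")
  expect_equal(nrow(cls), 2)
  expect_equal(cls$pixelId, 1:2)
})
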
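## Synthetic-data generators. Every generator takes an explicit seed (via its
## spec or argument), restores the caller's RNG state, and returns its ground
## truth alongside the data so downstream stages can be tested against known
## answers.

#' Generate an annual land-cover class-map stack
#'
#' Draws a per-pixel ecosystem class from `classFractions`, then converts
#' exactly `round(conversionFraction * nVegetated)` vegetated pixels to a
#' different vegetated class at a uniformly drawn interior year. All other
#' pixels keep their class in every year.
#'
#' @param spec A [LandscapeSpec-class].
#' @return List with `maps` (integer array `nRows x nCols x nYears` of
#'   [landcoverCodes()]), `years`, and `truth` (`converted` linear pixel
#'   indices, `conversionYear`, `fromClass`, `toClass`).
#' @examples
#' lc <- generateLandcover(landscapeSpec(10, 10, conversionFraction = 0.1, seed = 1))
#' dim(lc$maps)
#' @export
generateLandcover <- function(spec) {
  stopifnot(is(spec, "LandscapeSpec"))
  validObject(spec)
  npix <- spec@nRows * spec@nCols
  nyears <- length(spec@years)
  withSeed(spec@seed, {
    cls <- sample(names(spec@classFractions), npix, replace = TRUE,
                  prob = spec@classFractions)
    base <- LC_CODES[cls]
    veg <- which(base != LC_CODES[["nodata"]])
    nconv <- round(spec@conversionFraction * length(veg))
    maps <- array(rep(base, nyears), dim = c(spec@nRows, spec@nCols, nyears))
    truth <- list(converted = integer(0), conversionYear = integer(0),
                  fromClass = character(0), toClass = character(0))
    if (nconv > 0) {
      conv <- sort(sample(veg, nconv))
      # conversion year strictly interior so both classes are observed
      cy <- spec@years[sample(2:(nyears - 1), nconv, replace = TRUE)]
      from <- names(LC_CODES)[match(base[conv], LC_CODES)]
      to <- vapply(from, function(f)
        sample(setdiff(LC_CLASSES, f), 1L), character(1))
      for (i in seq_len(nconv)) {
        yrs <- which(spec@years >= cy[i])
        px <- arrayInd(conv[i], c(spec@nRows, spec@nCols))
        maps[px[1], px[2], yrs] <- LC_CODES[[to[i]]]
      }
      truth <- list(converted = conv, conversionYear = cy,
                    fromClass = unname(from), toClass = unname(to))
    }
    list(maps = maps, years = spec@years, truth = truth)
  })
}

# 12-month sinusoidal climatology evaluated at calendar months m (1..12);
# peak in July.
climatologyAt <- function(months, mean, amplitude) {
  mean + amplitude * sin(2 * pi * (months - 4) / 12)
}

#' Generate a climate-vegetation cube from the anomaly recursion
#'
#' Builds monthly temperature and precipitation series as a fixed 12-month
#' sinusoidal climatology plus white-noise anomalies, then evolves the NDVI
#' anomaly by the first-order recursion
#' \deqn{N_t = \alpha T_t + \beta P_t + \gamma N_{t-1} + \varepsilon_t}
#' with the coefficients in `params` (per-pixel, optionally drifting over
#' years when a trend is specified). The anomalies entering the recursion are
#' unit-scale; physical series add them to the climatology at the scales in
#' `params@seasonal$anomalySd`. A 24-month burn-in removes the transient from
#' the AR start.
#'
#' @param spec A [LandscapeSpec-class] (geometry, years, seed).
#' @param params A [ProcessParams-class].
#' @return A [ClimateVegCube-class] whose `metadata()$truth` holds the true
#'   per-pixel coefficients and the exact anomaly series
#'   (`truth$anomalies$ndvi/temperature/precipitation`) on which the
#'   recursion was run.
#' @export
generateClimateVeg <- function(spec, params) {
  stopifnot(is(spec, "LandscapeSpec"), is(params, "ProcessParams"))
  validObject(spec); validObject(params)
  years <- spec@years
  nyears <- length(years)
  nm <- 12L * nyears
  if (nm < 60L) stop("at least 60 months must be requested")
  npix <- spec@nRows * spec@nCols
  alpha <- rep_len(params@alphaTrue, npix)
  beta <- rep_len(params@betaTrue, npix)
  gamma <- rep_len(params@gammaTrue, npix)
  if (any(abs(gamma) >= 1)) stop("non-stationary gamma rejected")

  monthOf <- rep(1:12, nyears)
  yearOf <- rep(years, each = 12L)
  ts <- params@trendSpec
  drift <- switch(ts$type,
    none = rep(0, nyears),
    linear = ts$slope * (seq_len(nyears) - 1L),
    piecewise = {
      bi <- match(ts$breakYear, years)
      if (is.na(bi)) stop("trendSpec breakYear outside the year span")
      t1 <- pmin(seq_len(nyears), bi) - 1L
      t2 <- pmax(seq_len(nyears) - bi, 0L)
      ts$slope1 * t1 + ts$slope2 * t2
    })
  driftM <- drift[match(yearOf, years)]

  burn <- 24L
  withSeed(spec@seed, {
    # optionally only a fraction of pixels carries the planted drift
    frac <- ts$fraction %||% 1
    sel <- if (frac < 1) {
      s <- numeric(npix)
      s[sample.int(npix, round(frac * npix))] <- 1
      s
    } else rep(1, npix)
    zT <- matrix(rnorm(npix * (nm + burn)), npix)
    zP <- matrix(rnorm(npix * (nm + burn)), npix)
    eps <- matrix(rnorm(npix * (nm + burn), sd = params@noiseSd), npix)
    N <- matrix(0, npix, nm + burn)
    dAll <- c(rep(drift[1], burn), driftM)
    N[, 1] <- (alpha + sel * dAll[1]) * zT[, 1] +
      (beta + sel * dAll[1]) * zP[, 1] + eps[, 1]
    for (t in 2:(nm + burn)) {
      N[, t] <- (alpha + sel * dAll[t]) * zT[, t] +
        (beta + sel * dAll[t]) * zP[, t] +
        gamma * N[, t - 1] + eps[, t]
    }
    keep <- (burn + 1L):(nm + burn)
    N <- N[, keep, drop = FALSE]
    zT <- zT[, keep, drop = FALSE]
    zP <- zP[, keep, drop = FALSE]

    seas <- params@seasonal
    aSd <- seas$anomalySd
    climN <- climatologyAt(monthOf, seas$ndvi[["mean"]], seas$ndvi[["amplitude"]])
    climT <- climatologyAt(monthOf, seas$temperature[["mean"]],
                           seas$temperature[["amplitude"]])
    climP <- climatologyAt(monthOf, seas$precipitation[["mean"]],
                           seas$precipitation[["amplitude"]])
    ndvi <- sweep(aSd[["ndvi"]] * N, 2, climN, `+`)
    temp <- sweep(aSd[["temperature"]] * zT, 2, climT, `+`)
    pre <- pmax(sweep(aSd[["precipitation"]] * zP, 2, climP, `+`), 0)

    # nodata pixels carry NA throughout
    cls <- sample(names(spec@classFractions), npix, replace = TRUE,
                  prob = spec@classFractions)
    nd <- which(cls == "nodata")
    if (length(nd)) ndvi[nd, ] <- temp[nd, ] <- pre[nd, ] <- NA_real_

    truth <- list(alpha = alpha, beta = beta, gamma = gamma,
                  noiseSd = params@noiseSd, drift = drift,
                  driftPixels = which(sel > 0),
                  anomalies = list(ndvi = N, temperature = zT,
                                   precipitation = zP))
    climateVegCube(ndvi, temp, pre, years = yearOf, months = monthOf,
                   gridMeta = list(nRows = spec@nRows, nCols = spec@nCols,
                                   cellSize = 1, nodata = NA_real_),
                   truth = truth)
  })
}

#' Generate an annual vulnerability series with a planted trend
#'
#' Produces `pattern + Gaussian noise` over `nYears` years, where the
#' pattern is constant, linear, or a continuous two-segment piecewise line
#' with a planted break year.
#'
#' @param pattern One of `list(type = "none")`,
#'   `list(type = "linear", slope =)`, or
#'   `list(type = "piecewise", breakYear =, slope1 =, slope2 =)` with
#'   `breakYear` on the `years` scale.
#' @param nYears Series length (>= 11: room for two segments plus the break).
#' @param noiseSd Gaussian noise sd (0 allowed).
#' @param seed Integer seed.
#' @param baseLevel Series level at the first year (default 0.8, a typical
#'   mid-range VI).
#' @param years Calendar years (default `1985:(1984 + nYears)`).
#' @param minSegment Minimum years between a planted break and either end
#'   (default 3).
#' @return List with `series` (named by year), `years`, and `truth`
#'   (`type`, `breakYear`, `slopes`, `noiseSd`).
#' @export
generateViSeries <- function(pattern, nYears, noiseSd, seed,
                             baseLevel = 0.8, years = NULL, minSegment = 3L) {
  if (nYears < 11L) stop("nYears must be >= 11")
  if (is.null(years)) years <- 1985:(1984 + nYears)
  stopifnot(length(years) == nYears)
  tt <- seq_len(nYears) - 1L
  sig <- switch(pattern$type,
    none = rep(baseLevel, nYears),
    linear = baseLevel + pattern$slope * tt,
    piecewise = {
      bi <- match(pattern$breakYear, years)
      if (is.na(bi)) stop("breakYear must be one of the series years")
      if (bi < minSegment || nYears - bi + 1L < minSegment)
        stop("piecewise break too close to a series end")
      baseLevel + pattern$slope1 * pmin(tt, bi - 1L) +
        pattern$slope2 * pmax(tt - (bi - 1L), 0L)
    },
    stop("unknown pattern type: ", pattern$type))
  series <- withSeed(seed, sig + rnorm(nYears, sd = noiseSd))
  names(series) <- years
  truth <- list(type = pattern$type,
                breakYear = if (pattern$type == "piecewise") pattern$breakYear else NA,
                slopes = switch(pattern$type,
                                none = c(0, 0),
                                linear = c(pattern$slope, pattern$slope),
                                piecewise = c(pattern$slope1, pattern$slope2)),
                noiseSd = noiseSd)
  list(series = series, years = years, truth = truth)
}

# Overwrite each collinear child with an r-correlated copy of the
# equal-weight standardized combination of its parents. Consumes rnorm draws,
# so callers must run it inside withSeed().
plantCollinearity <- function(X, pairs, ranges) {
  for (p in pairs) {
    Z <- vapply(p$a, function(f) {
      x <- X[, f]
      (x - mean(x)) / sd(x)
    }, numeric(nrow(X)))
    comb <- rowSums(Z) / sqrt(ncol(Z))
    rgb <- ranges[[p$b]]
    sdb <- diff(rgb) / sqrt(12)          # match the uniform sd
    X[, p$b] <- mean(rgb) + sdb * (p$r * comb +
                                     sqrt(1 - p$r^2) * rnorm(nrow(X)))
  }
  X
}

# Planted per-feature effect curves used by generateDriverTable and by the
# end-to-end threshold tests.
shapeEffect <- function(x, rs) {
  switch(rs$shape,
    flat = rep(0, length(x)),
    linear = rs$slope * (x - mean(x)),
    step = ifelse(x < rs$threshold, rs$low, rs$high),
    v_shape = rs$slope * abs(x - rs$vertex),
    plateau = rs$slope * (pmin(x, rs$threshold) - rs$threshold),
    stop("unknown response shape: ", rs$shape))
}

#' Generate a driver feature table with planted effects
#'
#' Draws the candidate driver features uniformly on realistic natural-unit
#' ranges, overwrites the second member of each collinear pair with a
#' correlation-matched copy of the first, and builds the target as the sum
#' of the planted per-feature response curves plus Gaussian noise.
#'
#' @param spec A [DriverSpec-class].
#' @param nSamples Number of rows (>= 500). In `"pixel_mean"` mode the rows
#'   are grouped into pseudo-pixels of 10 pixel-years and averaged.
#' @param seed Integer seed.
#' @param unit `"pooled"` (pixel-year rows, default) or `"pixel_mean"`.
#' @return List with `features` (data frame), `target` (numeric), and
#'   `truth` (`shapes`, `noiseSd`, `signalSd`, `collinearPairs`).
#' @export
generateDriverTable <- function(spec, nSamples, seed,
                                unit = c("pooled", "pixel_mean")) {
  stopifnot(is(spec, "DriverSpec"))
  validObject(spec)
  unit <- match.arg(unit)
  if (nSamples < 500L) stop("nSamples must be >= 500")
  withSeed(seed, {
    X <- vapply(spec@featureNames, function(nm) {
      rg <- spec@featureRanges[[nm]]
      runif(nSamples, rg[1], rg[2])
    }, numeric(nSamples))
    colnames(X) <- spec@featureNames
    X <- plantCollinearity(X, spec@collinearPairs, spec@featureRanges)
    signal <- rowSums(vapply(spec@featureNames, function(nm)
      shapeEffect(X[, nm], spec@responseShapes[[nm]]), numeric(nSamples)))
    sSd <- sd(signal)
    # default: signal-to-noise 10:1; an all-flat (no-signal) design gets
    # unit noise so the target is still a random variable
    nSd <- if (is.na(spec@noiseSd)) {
      if (sSd > 0) 0.1 * sSd else 1
    } else spec@noiseSd
    target <- signal + rnorm(nSamples, sd = nSd)
    feat <- as.data.frame(X)
    if (unit == "pixel_mean") {
      grp <- rep(seq_len(ceiling(nSamples / 10)), each = 10L)[seq_len(nSamples)]
      feat <- stats::aggregate(feat, list(pixel = grp), mean)[, -1]
      target <- as.numeric(tapply(target, grp, mean))
    }
    list(features = feat, target = target,
         truth = list(shapes = spec@responseShapes, noiseSd = nSd,
                      signalSd = sSd, collinearPairs = spec@collinearPairs))
  })
}
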
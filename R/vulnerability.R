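## Sliding-window exposure-sensitivity-resilience vulnerability index.
##
## Per five-year window and pixel, the standardized monthly anomalies are
## regressed as  NDVI_t = alpha * Temp_t + beta * Pre_t + gamma * NDVI_{t-1}
## + eps_t  (OLS with intercept). The coefficients are min-max normalized
## across pixels within the window and combined into
##   EI = alpha + beta
##   SI = alpha * Tnorm + beta * Pnorm
##   RI = 1 - gamma
##   VI = EI * SI / (1 + RI)
## where Tnorm/Pnorm are the min-max-normalized window means of raw
## temperature and precipitation.

#' Enumerate sliding windows
#'
#' Contiguous windows `[y, y + length - 1]` advanced by `step` years; each
#' window is assigned to its center year (`y + (length - 1) / 2`), so a
#' 5-year window starting in 1983 is recorded at 1985 and a 1983-2022 span
#' yields 36 windows centered 1985-2020.
#'
#' @param firstYear,lastYear Span of available years (inclusive).
#' @param length Window length in years (default 5).
#' @param step Step between window starts in years (default 1).
#' @return Data frame with `windowId`, `startYear`, `endYear`, `centerYear`.
#' @examples
#' nrow(enumerateWindows(1983, 2022))  # 36
#' @export
enumerateWindows <- function(firstYear, lastYear, length = 5L, step = 1L) {
  span <- lastYear - firstYear + 1L
  if (span < length) stop("year span shorter than the window length")
  starts <- seq(firstYear, lastYear - length + 1L, by = step)
  data.frame(windowId = seq_along(starts),
             startYear = starts,
             endYear = starts + length - 1L,
             centerYear = starts + (length - 1L) %/% 2L)
}

#' Fit the windowed NDVI anomaly regression for one pixel
#'
#' Ordinary least squares of `NDVI_t` on `(Temp_t, Pre_t, NDVI_{t-1})` over
#' `t = 2 ... n` with an intercept (the intercept is retained even though
#' standardized inputs are centered; it guards against numerical drift and
#' is immaterial for the coefficients). One observation is lost to the lag.
#' Rank-deficient designs are flagged invalid rather than raising.
#'
#' @param ndvi,temp,pre Equal-length numeric series for one pixel-window
#'   (typically 60 standardized months).
#' @return List: `alpha`, `beta`, `gamma`, `intercept`, `residualSd`,
#'   `nObs`, `valid`.
#' @export
fitWindowModel <- function(ndvi, temp, pre) {
  n <- length(ndvi)
  stopifnot(length(temp) == n, length(pre) == n)
  bad <- list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
              intercept = NA_real_, residualSd = NA_real_,
              nObs = n - 1L, valid = FALSE)
  if (n < 6L || anyNA(ndvi) || anyNA(temp) || anyNA(pre)) return(bad)
  y <- ndvi[-1L]
  X <- cbind(1, temp[-1L], pre[-1L], ndvi[-n])
  qx <- qr(X)
  if (qx$rank < 4L) return(bad)
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  list(alpha = unname(cf[2]), beta = unname(cf[3]), gamma = unname(cf[4]),
       intercept = unname(cf[1]),
       residualSd = sqrt(sum(res^2) / (length(y) - 4L)),
       nObs = n - 1L, valid = TRUE)
}

#' Min-max normalize window coefficients across pixels
#'
#' Scales each coefficient channel (alpha, beta, gamma) to `[0, 1]` over the
#' valid pixels of one window: the most negative coefficient maps to 0 and
#' the largest to 1, preserving ranks (negative raw coefficients are not
#' truncated). A channel with a degenerate range is set to 0.5 everywhere
#' with a warning.
#'
#' @param coefs Matrix or data frame with columns `alpha`, `beta`, `gamma`;
#'   one row per pixel. `NA` rows (invalid fits) pass through as `NA`.
#' @return Matrix with columns `alpha`, `beta`, `gamma` in `[0, 1]`.
#' @export
normalizeCoefficients <- function(coefs) {
  coefs <- as.matrix(coefs[, c("alpha", "beta", "gamma")])
  ok <- rowSums(is.na(coefs)) == 0L
  if (sum(ok) < 1L) stop("no valid fits to normalize")
  out <- coefs
  for (ch in colnames(coefs)) out[, ch] <- minMaxScale(coefs[, ch])
  out
}

#' Window-mean hydrothermal state, normalized across pixels
#'
#' Takes the per-pixel mean of raw temperature and precipitation over one
#' window and min-max normalizes each across all pixels of that window, so
#' 0 marks the coolest/driest pixel and 1 the warmest/wettest. Degenerate
#' (spatially uniform) fields collapse to 0.5 with a warning.
#'
#' @param tempSlice,preSlice Pixel-by-month matrices of raw (unstandardized)
#'   values for one window.
#' @return List with `tNorm` and `pNorm`, numeric per pixel.
#' @export
computeHydrothermalNorms <- function(tempSlice, preSlice) {
  tempSlice <- asPixelMatrix(tempSlice)
  preSlice <- asPixelMatrix(preSlice)
  list(tNorm = minMaxScale(rowMeans(tempSlice)),
       pNorm = minMaxScale(rowMeans(preSlice)))
}

#' Combine normalized coefficients into the vulnerability indices
#'
#' Pure index algebra on normalized inputs:
#' `EI = alphaN + betaN`; `SI = alphaN * tNorm + betaN * pNorm`;
#' `RI = 1 - gammaN`; `VI = EI * SI / (1 + RI)`. With all inputs in
#' `[0, 1]`, `EI, SI <= 2`, `RI` lies in `[0, 1]` and `VI` in `[0, 4]`.
#'
#' @param alphaN,betaN,gammaN,tNorm,pNorm Numeric vectors in `[0, 1]`
#'   (recycled to a common length); `NA` propagates.
#' @return Data frame with columns `EI`, `SI`, `RI`, `VI`.
#' @examples
#' computeIndices(1, 1, 0, 1, 1)  # EI = SI = VI = 2, RI = 1
#' @export
computeIndices <- function(alphaN, betaN, gammaN, tNorm, pNorm) {
  n <- max(length(alphaN), length(betaN), length(gammaN),
           length(tNorm), length(pNorm))
  a <- rep_len(alphaN, n); b <- rep_len(betaN, n); g <- rep_len(gammaN, n)
  tn <- rep_len(tNorm, n); pn <- rep_len(pNorm, n)
  rng <- range(c(a, b, g, tn, pn), na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    stop("computeIndices expects normalized inputs in [0, 1]")
  EI <- a + b
  SI <- a * tn + b * pn
  RI <- 1 - g
  data.frame(EI = EI, SI = SI, RI = RI, VI = EI * SI / (1 + RI))
}

#' Build the annual vulnerability series for a cube
#'
#' Runs the full per-window chain over a [ClimateVegCube-class]: slice each
#' five-year window, standardize the three variables within it
#' ([standardizeWindow()]), fit the anomaly regression per pixel
#' ([fitWindowModel()]), min-max normalize the coefficients and the window
#' hydrothermal means across pixels, and evaluate the indices
#' ([computeIndices()]). Each window's record is stored at its center year;
#' invalid pixel-windows emit `NA`.
#'
#' @param cube A [ClimateVegCube-class].
#' @param windowLength,windowStep Window geometry in years (defaults 5, 1).
#' @param deseasonalize Passed to [standardizeWindow()].
#' @param normalizationScope `"window"` (min-max across pixels within each
#'   window, default) or `"pooled"` (a single min-max per channel across all
#'   windows). The scope changes how interannual VI trends read: per-window
#'   scaling makes each annual map internally comparable, pooled scaling
#'   preserves between-window coefficient drift.
#' @return A [VulnerabilitySeries-class].
#' @export
buildViSeries <- function(cube, windowLength = 5L, windowStep = 1L,
                          deseasonalize = TRUE,
                          normalizationScope = c("window", "pooled")) {
  stopifnot(is(cube, "ClimateVegCube"))
  normalizationScope <- match.arg(normalizationScope)
  cd <- colData(cube)
  wins <- enumerateWindows(min(cd$year), max(cd$year),
                           length = windowLength, step = windowStep)
  npix <- nrow(cube)
  nwin <- nrow(wins)
  ndvi <- assay(cube, "ndvi")
  temp <- assay(cube, "temperature")
  pre <- assay(cube, "precipitation")

  rawA <- rawB <- rawG <- matrix(NA_real_, npix, nwin)
  tMean <- pMean <- matrix(NA_real_, npix, nwin)
  for (w in seq_len(nwin)) {
    cols <- which(cd$year >= wins$startYear[w] & cd$year <= wins$endYear[w])
    mo <- cd$month[cols]
    sN <- standardizeWindow(ndvi[, cols, drop = FALSE], mo, deseasonalize)
    sT <- standardizeWindow(temp[, cols, drop = FALSE], mo, deseasonalize)
    sP <- standardizeWindow(pre[, cols, drop = FALSE], mo, deseasonalize)
    ok <- sN$valid & sT$valid & sP$valid
    for (p in which(ok)) {
      f <- fitWindowModel(sN$values[p, ], sT$values[p, ], sP$values[p, ])
      if (f$valid) {
        rawA[p, w] <- f$alpha; rawB[p, w] <- f$beta; rawG[p, w] <- f$gamma
      }
    }
    tMean[, w] <- rowMeans(temp[, cols, drop = FALSE])
    pMean[, w] <- rowMeans(pre[, cols, drop = FALSE])
  }

  EI <- SI <- RI <- VI <- tN <- pN <- matrix(NA_real_, npix, nwin)
  if (normalizationScope == "window") {
    for (w in seq_len(nwin)) {
      if (all(is.na(rawA[, w]))) next
      aN <- minMaxScale(rawA[, w]); bN <- minMaxScale(rawB[, w])
      gN <- minMaxScale(rawG[, w])
      tN[, w] <- minMaxScale(tMean[, w]); pN[, w] <- minMaxScale(pMean[, w])
      idx <- computeIndices(aN, bN, gN, tN[, w], pN[, w])
      EI[, w] <- idx$EI; SI[, w] <- idx$SI; RI[, w] <- idx$RI; VI[, w] <- idx$VI
    }
  } else {
    aN <- matrix(minMaxScale(rawA), npix); bN <- matrix(minMaxScale(rawB), npix)
    gN <- matrix(minMaxScale(rawG), npix)
    tN <- matrix(minMaxScale(tMean), npix); pN <- matrix(minMaxScale(pMean), npix)
    idx <- computeIndices(as.numeric(aN), as.numeric(bN), as.numeric(gN),
                          as.numeric(tN), as.numeric(pN))
    EI <- matrix(idx$EI, npix); SI <- matrix(idx$SI, npix)
    RI <- matrix(idx$RI, npix); VI <- matrix(idx$VI, npix)
  }

  se <- SummarizedExperiment(
    assays = list(EI = EI, SI = SI, RI = RI, VI = VI, tNorm = tN, pNorm = pN),
    rowData = rowData(cube),
    colData = DataFrame(centerYear = wins$centerYear,
                        startYear = wins$startYear, endYear = wins$endYear))
  out <- new("VulnerabilitySeries", se)
  metadata(out) <- c(metadata(cube),
                     list(windowLength = windowLength, windowStep = windowStep,
                          normalizationScope = normalizationScope,
                          rawCoefficients = list(alpha = rawA, beta = rawB,
                                                 gamma = rawG)))
  out
}
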
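## Interannual trend classification of annual VI series: coefficient of
## variation, three candidate change models (simple linear, continuous
## piecewise linear, Pettitt change point), an AIC decision cascade, and a
## boundary re-evaluation rule for turning points too close to the series
## ends.

# Least squares with coefficient covariance, via QR. Returns NULL on rank
# deficiency.
olsFit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- chol2inv(qr.R(qx))
  list(coef = as.numeric(cf), rss = rss, df = df,
       vcov = sigma2 * XtXinv)
}

tTestP <- function(est, se, df) {
  if (!is.finite(se) || se <= 0 || df <= 0) return(1)
  2 * pt(abs(est / se), df, lower.tail = FALSE)
}

#' Coefficient of variation of an annual series
#'
#' `cv = 100 * sd / mean` (sample sd), binned into low (`<20`), moderate
#' (`20-30`) and high (`>30`) percent variability. Series with mean at or
#' below `eps` are flagged invalid and excluded from binning.
#'
#' @param series Numeric vector of annual values (VI is non-negative by
#'   construction).
#' @param eps Smallest admissible mean (default `1e-8`).
#' @return List: `cvPercent`, `cvBin` (factor level or `NA`), `valid`.
#' @examples
#' coefficientOfVariation(c(1, 1, 1, 3))  # 66.7%, bin ">30"
#' @export
coefficientOfVariation <- function(series, eps = 1e-8) {
  m <- mean(series)
  if (!is.finite(m) || m <= eps)
    return(list(cvPercent = NA_real_, cvBin = NA_character_, valid = FALSE))
  cv <- 100 * sd(series) / m
  bin <- if (cv < 20) "<20" else if (cv <= 30) "20-30" else ">30"
  list(cvPercent = cv, cvBin = bin, valid = TRUE)
}

#' Simple linear trend fit
#'
#' OLS of the series on year; the p-value is the two-sided t-test on the
#' slope and the AIC is the Gaussian least-squares form
#' `n log(RSS/n) + 2k` with `k = 3` (intercept, slope, variance). A
#' zero-variance series returns slope 0 with p = 1.
#'
#' @param series Annual values.
#' @param years Corresponding years (default consecutive integers).
#' @return List: `slope`, `intercept`, `p`, `aic`, `rss`.
#' @export
fitLinear <- function(series, years = seq_along(series)) {
  n <- length(series)
  stopifnot(n >= 3L, length(years) == n)
  if (sd(series) <= .Machine$double.eps^0.5) {
    return(list(slope = 0, intercept = mean(series), p = 1,
                aic = aicFromRss(0, n, 3L), rss = 0))
  }
  f <- olsFit(cbind(1, years), series)
  p <- tTestP(f$coef[2], sqrt(f$vcov[2, 2]), f$df)
  list(slope = f$coef[2], intercept = f$coef[1], p = p,
       aic = aicFromRss(f$rss, n, 3L), rss = f$rss)
}

#' Continuous piecewise-linear (broken-stick) fit
#'
#' Exhaustive search over admissible break years: for each candidate the
#' hinge model `y = a + b1 * t + b2 * (t - t_break)+` is fit by OLS and the
#' break minimizing RSS is chosen. Both segments must contain at least
#' `minSegment` points (the break year belongs to both). Segment slopes and
#' their p-values come from separate per-segment regressions at the chosen
#' break: each segment's trend is t-tested on that segment's own data,
#' which keeps the significance honest under the RSS-driven break selection
#' (t-statistics read off the hinge fit are inflated by the search). AIC is
#' computed from the continuous hinge fit with `k = 5` (intercept, two
#' slopes, break, variance).
#'
#' @param series Annual values.
#' @param years Corresponding years.
#' @param minSegment Minimum points per segment (default 5, mirroring the
#'   five-year boundary-exclusion rule).
#' @return List with `available`; when `TRUE` also `breakYear`, `breakIndex`,
#'   `slopes` (length 2), `pValues` (length 2), `aic`, `rss`.
#' @export
fitPiecewise <- function(series, years = seq_along(series), minSegment = 5L) {
  n <- length(series)
  stopifnot(length(years) == n)
  if (n < 2L * minSegment + 1L) return(list(available = FALSE))
  cand <- seq.int(minSegment, n - minSegment + 1L)
  best <- NULL
  for (bi in cand) {
    hin <- pmax(years - years[bi], 0)
    f <- olsFit(cbind(1, years, hin), series)
    if (is.null(f)) next
    if (is.null(best) || f$rss < best$rss) best <- c(f, list(bi = bi))
  }
  if (is.null(best)) return(list(available = FALSE))
  bi <- best$bi
  seg1 <- fitLinear(series[seq_len(bi)], years[seq_len(bi)])
  seg2 <- fitLinear(series[bi:n], years[bi:n])
  list(available = TRUE,
       breakYear = years[bi], breakIndex = bi,
       slopes = c(seg1$slope, seg2$slope),
       pValues = c(seg1$p, seg2$p),
       aic = aicFromRss(best$rss, n, 5L), rss = best$rss)
}

#' Pettitt change-point test
#'
#' Rank-based nonparametric test built from sequential Mann-Whitney
#' statistics: `U_t = sum_{i<=t} sum_{j>t} sign(x_j - x_i)`, `K = max |U_t|`,
#' change point at the argmax, with the asymptotic significance
#' approximation `p = 2 exp(-6 K^2 / (n^3 + n^2))` capped at 1. Ties
#' contribute 0. For comparability with the regression candidates an AIC is
#' attached from a two-mean step model split at the change point
#' (`k = 4`: two means, change point, variance).
#'
#' @param series Annual values (`n >= 8`).
#' @param years Corresponding years.
#' @return List: `changeYear`, `changeIndex`, `k` (the K statistic), `u`
#'   (the full U_t trace, length n-1), `p`, `aic`, `rss`.
#' @export
pettittTest <- function(series, years = seq_along(series)) {
  n <- length(series)
  stopifnot(n >= 8L, length(years) == n)
  sgn <- sign(outer(series, series, FUN = function(a, b) b - a)) # sgn[i,j] = sign(x_j - x_i)
  u <- vapply(seq_len(n - 1L), function(t)
    sum(sgn[seq_len(t), (t + 1L):n]), numeric(1))
  ci <- which.max(abs(u))
  K <- abs(u[ci])
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  rss <- sum((series[1:ci] - mean(series[1:ci]))^2) +
    sum((series[(ci + 1L):n] - mean(series[(ci + 1L):n]))^2)
  list(changeYear = years[ci], changeIndex = ci, k = K, u = u, p = p,
       aic = aicFromRss(rss, n, 4L), rss = rss)
}

# Per-segment OLS slopes around a Pettitt change point; used to decide
# whether a step winner carries two significant opposite trends.
segmentSlopes <- function(series, years, ci, alpha) {
  seg <- function(idx) {
    if (length(idx) < 3L) return(list(slope = 0, p = 1))
    f <- fitLinear(series[idx], years[idx])
    list(slope = f$slope, p = f$p)
  }
  s1 <- seg(seq_len(ci))
  s2 <- seg((ci + 1L):length(series))
  list(slopes = c(s1$slope, s2$slope), pValues = c(s1$p, s2$p),
       bothSig = s1$p < alpha && s2$p < alpha)
}

#' Classify the trend regime of one annual VI series
#'
#' Decision cascade over the three candidate models:
#' \enumerate{
#'   \item Fit simple linear, piecewise linear and Pettitt models.
#'   \item No model significant (all `p >= alpha`) gives `no_trend`. The
#'     piecewise candidate counts as significant only when *both* segment
#'     slopes have `p < alpha`.
#'   \item Exactly one significant model wins; with several, the lowest AIC
#'     wins, ties going to the simpler model (linear before piecewise before
#'     the Pettitt step).
#'   \item A winning turning point within `boundaryYears` of either series
#'     end triggers a linear re-evaluation: significant slope gives a linear
#'     class by sign, otherwise `no_trend`.
#'   \item An interior abrupt winner is labeled `I_D` (significant increase
#'     then decrease) or `D_I` (decrease then increase) from its segment
#'     slopes; same-sign segments fall back to the linear re-evaluation.
#' }
#'
#' @param series Annual VI values.
#' @param years Corresponding years (e.g. 1985:2020 center years).
#' @param alpha Significance level (default 0.05).
#' @param minSegment Minimum piecewise segment length in years (default 5).
#' @param boundaryYears Exclusion distance from the series ends for turning
#'   points, inclusive (default 5: turning years in `[first, first+5]` or
#'   `[last-5, last]` are re-evaluated).
#' @return One-row data frame with the [TrendClassification-class] columns.
#' @export
classifyTrend <- function(series, years = seq_along(series), alpha = 0.05,
                          minSegment = 5L, boundaryYears = 5L) {
  n <- length(series)
  empty <- data.frame(pixelId = NA_integer_, cvPercent = NA_real_,
                      cvBin = NA_character_, trendType = NA_character_,
                      turningPattern = NA_character_, turningYear = NA_integer_,
                      turningBin = NA_character_, modelChosen = NA_character_,
                      slope1 = NA_real_, slope2 = NA_real_,
                      pLinear = NA_real_, pPiecewise = NA_real_,
                      pPettitt = NA_real_, aicLinear = NA_real_,
                      aicPiecewise = NA_real_, aicPettitt = NA_real_,
                      stringsAsFactors = FALSE)
  if (anyNA(series) || n < 8L) return(empty)

  cv <- coefficientOfVariation(series)
  lin <- fitLinear(series, years)
  pw <- fitPiecewise(series, years, minSegment)
  pet <- pettittTest(series, years)

  out <- empty
  out$cvPercent <- cv$cvPercent
  out$cvBin <- cv$cvBin
  out$pLinear <- lin$p
  out$aicLinear <- lin$aic
  out$pPettitt <- pet$p
  out$aicPettitt <- pet$aic
  if (pw$available) {
    out$pPiecewise <- max(pw$pValues)
    out$aicPiecewise <- pw$aic
  }

  sigLin <- lin$p < alpha
  sigPw <- pw$available && all(pw$pValues < alpha)
  sigPet <- pet$p < alpha

  linearBySign <- function(o) {
    if (sigLin) {
      o$trendType <- if (lin$slope > 0) "linear_increase" else "linear_decrease"
      o$modelChosen <- "linear"
      o$slope1 <- o$slope2 <- lin$slope
    } else {
      o$trendType <- "no_trend"
      o$modelChosen <- "none"
    }
    o$turningPattern <- "none"
    o
  }

  if (!sigLin && !sigPw && !sigPet) {
    out$trendType <- "no_trend"
    out$turningPattern <- "none"
    out$modelChosen <- "none"
    return(out)
  }

  # lowest AIC among significant candidates; ties to the simpler model,
  # encoded by candidate order linear < piecewise < pettitt
  cand <- data.frame(model = c("linear", "piecewise", "pettitt"),
                     sig = c(sigLin, sigPw, sigPet),
                     aic = c(lin$aic, if (pw$available) pw$aic else Inf, pet$aic))
  cand <- cand[cand$sig, , drop = FALSE]
  winner <- cand$model[which.min(cand$aic)]

  nearBoundary <- function(ty)
    ty <= years[1] + boundaryYears || ty >= years[n] - boundaryYears

  if (winner == "linear") return(linearBySign(out))

  if (winner == "piecewise") {
    ty <- pw$breakYear
    if (nearBoundary(ty)) return(linearBySign(out))
    s <- pw$slopes
    if (sign(s[1]) == sign(s[2])) return(linearBySign(out))
    out$trendType <- "abrupt"
    out$modelChosen <- "piecewise"
    out$turningYear <- as.integer(ty)
    out$turningPattern <- if (s[1] > 0) "I_D" else "D_I"
    out$slope1 <- s[1]; out$slope2 <- s[2]
    return(out)
  }

  # Pettitt winner: abrupt only when its two segments carry significant
  # opposite trends; otherwise the step is re-read as linear/no-trend.
  ty <- pet$changeYear
  if (nearBoundary(ty)) return(linearBySign(out))
  ss <- segmentSlopes(series, years, pet$changeIndex, alpha)
  if (!ss$bothSig || sign(ss$slopes[1]) == sign(ss$slopes[2]))
    return(linearBySign(out))
  out$trendType <- "abrupt"
  out$modelChosen <- "pettitt"
  out$turningYear <- as.integer(ty)
  out$turningPattern <- if (ss$slopes[1] > 0) "I_D" else "D_I"
  out$slope1 <- ss$slopes[1]; out$slope2 <- ss$slopes[2]
  out
}

#' Classify every pixel of a vulnerability series
#'
#' Applies [classifyTrend()] to each pixel row of a
#' [VulnerabilitySeries-class] (or a plain pixel-by-year matrix) and labels
#' turning-year bins.
#'
#' @param vi A [VulnerabilitySeries-class] or numeric matrix (pixels x
#'   years).
#' @param years Years of the columns; taken from `colData` when `vi` is a
#'   `VulnerabilitySeries`.
#' @param ... Passed to [classifyTrend()].
#' @param binEdges Turning-year bin edges (default `seq(1990, 2015, 5)`).
#' @return A [TrendClassification-class].
#' @export
classifyTrends <- function(vi, years = NULL, ..., binEdges = seq(1990, 2015, 5)) {
  if (is(vi, "VulnerabilitySeries")) {
    years <- colData(vi)$centerYear
    vi <- vulnerability(vi)
  }
  stopifnot(is.matrix(vi), length(years) == ncol(vi))
  rows <- lapply(seq_len(nrow(vi)), function(p) {
    r <- classifyTrend(vi[p, ], years, ...)
    r$pixelId <- p
    r
  })
  df <- do.call(rbind, rows)
  df$turningBin <- labelTurningBin(df$turningYear, binEdges)
  new("TrendClassification", DataFrame(df))
}

labelTurningBin <- function(turningYear, binEdges) {
  labs <- paste0(binEdges[-length(binEdges)], "-", binEdges[-1])
  idx <- findInterval(turningYear, binEdges, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(turningYear))
  ok <- !is.na(turningYear) & idx >= 1 & idx <= length(labs)
  out[ok] <- labs[idx[ok]]
  out
}

#' Bin turning years into five-year intervals
#'
#' Histograms the turning years of abrupt pixels into five-year intervals
#' (left-closed, last interval closed) and reports counts and percentages of
#' the total valid area.
#'
#' @param classifications A [TrendClassification-class] or data frame with
#'   `trendType` and `turningYear`.
#' @param binEdges Interval edges (default `seq(1990, 2015, 5)`).
#' @return Data frame with `bin`, `count`, `areaPercent` (share of all
#'   classified pixels).
#' @export
binTurningYears <- function(classifications, binEdges = seq(1990, 2015, 5)) {
  df <- as.data.frame(classifications)
  ab <- df[!is.na(df$trendType) & df$trendType == "abrupt", , drop = FALSE]
  labs <- paste0(binEdges[-length(binEdges)], "-", binEdges[-1])
  if (!nrow(ab))
    return(data.frame(bin = character(0), count = integer(0),
                      areaPercent = numeric(0)))
  bins <- labelTurningBin(ab$turningYear, binEdges)
  total <- sum(!is.na(df$trendType))
  counts <- table(factor(bins, levels = labs))
  data.frame(bin = labs, count = as.integer(counts),
             areaPercent = 100 * as.integer(counts) / total)
}
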
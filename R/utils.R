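#' @importFrom stats lm pt qnorm rnorm runif sd var coef vcov predict
#' @importFrom methods new validObject is slot
NULL

# Evaluate expr under a local RNG seed, restoring global state afterwards.
# All generators route randomness through this so no call mutates the
# caller's random stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Min-max scale a vector to [0, 1]
#'
#' Linearly maps the finite values of `x` so the minimum becomes 0 and the
#' maximum becomes 1. When the range is degenerate (all values equal) every
#' value is set to 0.5 and a warning is raised; this mirrors how a flat
#' coefficient field carries no ranking information.
#'
#' @param x Numeric vector; `NA`s pass through.
#' @param warn Emit a warning on a degenerate range (default `TRUE`).
#' @return Numeric vector in `[0, 1]`, same length as `x`.
#' @export
minMaxScale <- function(x, warn = TRUE) {
  r <- range(x, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(r)) || r[2] - r[1] <= 0) {
    if (warn) warning("degenerate range in min-max scaling; returning 0.5")
    out <- rep.int(0.5, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - r[1]) / (r[2] - r[1])
}

# Gaussian log-likelihood AIC for a least-squares fit: n*log(RSS/n) + 2k,
# where k counts mean parameters plus the variance.
aicFromRss <- function(rss, n, k) {
  rss <- max(rss, .Machine$double.xmin)
  n * log(rss / n) + 2 * k
}

# Land-cover integer code table (0 reserved for nodata).
LC_CODES <- c(nodata = 0L, cropland = 1L, forest = 2L, shrubland = 3L,
              grassland = 4L, wetland = 5L)
LC_CLASSES <- names(LC_CODES)[-1]

#' Land-cover code table
#'
#' Integer codes used in all class-map stacks and masks: 0 = nodata,
#' 1 = cropland, 2 = forest, 3 = shrubland, 4 = grassland, 5 = wetland.
#' Stable-pixel masks additionally use -1 for pixels whose class changed.
#'
#' @return Named integer vector of codes.
#' @export
landcoverCodes <- function() LC_CODES
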
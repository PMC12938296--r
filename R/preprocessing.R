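## Preprocessing: compositing, resampling, stable-pixel masking and
## within-window standardization. Grids are pixel-major matrices
## (pixels x layers) or row x col (x layer) arrays; NA is the nodata
## sentinel throughout. Pixel order is column-major over the row x col grid,
## matching the rowData of a ClimateVegCube.

asPixelMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L)
    return(matrix(x, nrow = dim(x)[1] * dim(x)[2]))
  if (is.numeric(x)) return(matrix(x, nrow = 1L))
  stop("expected a matrix, 3-d array or numeric vector")
}

#' Maximum value composite
#'
#' Aggregates sub-monthly (e.g. biweekly) NDVI layers to a monthly stack by
#' taking, per pixel and month, the maximum over that month's layers with
#' nodata ignored. A pixel-month whose layers are all nodata is nodata; a
#' month with no layers at all is an error.
#'
#' @param stack Pixel-by-layer matrix (or `row x col x layer` array) of
#'   sub-monthly values; `NA` = nodata.
#' @param groups Vector of length `ncol(stack)` assigning each layer to its
#'   calendar month (any label, e.g. `"1983-01"`); order of first appearance
#'   is preserved.
#' @return Pixel-by-month matrix with one column per unique group, columns
#'   named by group.
#' @examples
#' m <- rbind(c(0.40, 0.55, 0.30, NA))
#' maxValueComposite(m, c("jan", "jan", "feb", "feb"))
#' @export
maxValueComposite <- function(stack, groups) {
  m <- asPixelMatrix(stack)
  if (length(groups) != ncol(m))
    stop("'groups' must assign every layer to a month")
  ug <- unique(groups)
  out <- matrix(NA_real_, nrow(m), length(ug), dimnames = list(NULL, as.character(ug)))
  for (i in seq_along(ug)) {
    cols <- which(groups == ug[i])
    if (!length(cols)) stop("month with zero layers")
    sub <- m[, cols, drop = FALSE]
    mx <- do.call(pmax, c(asplit(sub, 2), list(na.rm = TRUE)))
    mx[!is.finite(mx)] <- NA_real_
    out[, i] <- mx
  }
  out
}

#' Nearest-neighbour resampling
#'
#' Regrids a single-band raster to a new cell size over the same extent.
#' Each target cell takes the value of the source cell containing the target
#' cell's center; values are never interpolated, so the operation is safe
#' for categorical rasters and is the identity at equal geometry.
#'
#' @param grid Numeric or integer matrix (rows from the top edge, grid
#'   north-up).
#' @param srcCell Source cell size (any length unit).
#' @param dstCell Target cell size, same unit.
#' @return Matrix on the target geometry.
#' @examples
#' resampleNearest(matrix(1:4, 2, 2), srcCell = 2, dstCell = 1)
#' @export
resampleNearest <- function(grid, srcCell, dstCell) {
  stopifnot(is.matrix(grid), srcCell > 0, dstCell > 0)
  h <- nrow(grid) * srcCell
  w <- ncol(grid) * srcCell
  nr <- as.integer(round(h / dstCell))
  nc <- as.integer(round(w / dstCell))
  if (nr < 1L || nc < 1L) stop("empty overlap between source and target grids")
  # centers of target cells, measured from the shared top-left origin
  ry <- (seq_len(nr) - 0.5) * dstCell
  cx <- (seq_len(nc) - 0.5) * dstCell
  si <- pmin(pmax(ceiling(ry / srcCell), 1L), nrow(grid))
  sj <- pmin(pmax(ceiling(cx / srcCell), 1L), ncol(grid))
  grid[si, sj, drop = FALSE]
}

#' Stable-pixel ecosystem mask
#'
#' Labels each pixel with its ecosystem class code if the class is identical
#' in every input year, with -1 (unstable) if it changed, and 0 (nodata) if
#' it is nodata throughout. Analyses stratified by ecosystem are restricted
#' to stable pixels so that class comparisons are not confounded by
#' land-cover conversion.
#'
#' @param classStack Integer array `nRows x nCols x nYears` of
#'   [landcoverCodes()], or a list of equally sized matrices.
#' @return Integer matrix `nRows x nCols`; codes as in [landcoverCodes()]
#'   plus -1 for unstable.
#' @export
stablePixelMask <- function(classStack) {
  if (is.list(classStack)) {
    dims <- unique(lapply(classStack, dim))
    if (length(dims) != 1L) stop("inconsistent grid geometry across years")
    classStack <- array(unlist(classStack),
                        dim = c(dims[[1]], length(classStack)))
  }
  d <- dim(classStack)
  if (length(d) != 3L || d[3] < 2L) stop("need >= 2 annual class maps")
  m <- matrix(classStack, nrow = d[1] * d[2])
  stable <- rowSums(m == m[, 1]) == ncol(m)
  out <- ifelse(stable, m[, 1], -1L)
  matrix(as.integer(out), d[1], d[2])
}

#' Within-window standardization of monthly series
#'
#' For each pixel and variable inside a sliding window, removes the
#' month-of-year mean computed within that window (deseasonalization) and
#' then z-scores the residual to mean 0, sd 1 over the window. Pixels whose
#' deseasonalized series has zero variance, or that contain any nodata month,
#' are flagged invalid rather than raising an error; downstream stages skip
#' them.
#'
#' @param slice Pixel-by-month matrix covering exactly one window (e.g. 60
#'   months), or a single series as a vector.
#' @param months Calendar month (1-12) of each column.
#' @param deseasonalize Remove the within-window monthly climatology first
#'   (default `TRUE`); `FALSE` z-scores the raw values.
#' @return List with `values` (standardized matrix, invalid rows all-`NA`)
#'   and `valid` (logical per pixel).
#' @export
standardizeWindow <- function(slice, months, deseasonalize = TRUE) {
  m <- asPixelMatrix(slice)
  if (length(months) != ncol(m))
    stop("'months' must label every column of the window slice")
  valid <- rowSums(is.na(m)) == 0L
  x <- m
  if (deseasonalize) {
    for (mo in unique(months)) {
      cols <- which(months == mo)
      mu <- rowMeans(m[, cols, drop = FALSE])
      x[, cols] <- m[, cols, drop = FALSE] - mu
    }
  }
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  degenerate <- !is.na(s) & s <= .Machine$double.eps^0.5
  valid <- valid & !degenerate
  out <- (x - mu) / s
  out[!valid, ] <- NA_real_
  list(values = out, valid = valid)
}
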
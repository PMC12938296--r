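## Driver analysis: iterative VIF screening, seeded grid-search gradient
## boosting, exact tree-SHAP attribution, partial dependence and
## piecewise-linear threshold readout.

#' @importFrom xgboost xgb.DMatrix xgb.train xgb.cv
#' @importFrom stats quantile
NULL

#' Iterative variance-inflation-factor screening
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` for every current feature (feature j
#' regressed on all others, with intercept), drops the single highest-VIF
#' feature if it is at or above the cutoff, and repeats until all remaining
#' VIFs fall below the cutoff. Ties at the maximum drop the later column
#' first. Screening the retained set again removes nothing (idempotence).
#'
#' @param X Numeric data frame or matrix of candidate features (`n` rows
#'   must exceed the number of features).
#' @param cutoff Exclusion threshold (default 10).
#' @return List: `retained` (names, input order), `dropped` (names, drop
#'   order), `vifReport` (data frame of `round`, `feature`, `vif`).
#' @export
vifScreen <- function(X, cutoff = 10) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2L, nrow(X) > ncol(X))
  feats <- colnames(X)
  if (is.null(feats)) stop("features must be named")
  report <- list()
  dropped <- character(0)
  round <- 0L
  repeat {
    round <- round + 1L
    vifs <- vapply(feats, function(f) {
      others <- setdiff(feats, f)
      y <- X[, f]
      fit <- olsFit(cbind(1, X[, others, drop = FALSE]), y)
      if (is.null(fit)) return(Inf)
      r2 <- 1 - fit$rss / sum((y - mean(y))^2)
      if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    report[[round]] <- data.frame(round = round, feature = feats,
                                  vif = unname(vifs), row.names = NULL)
    worst <- max(vifs)
    if (worst < cutoff || length(feats) <= 1L) break
    # ties at the max drop the later column first
    at <- which(vifs >= worst - 1e-12)
    drop <- feats[at[length(at)]]
    dropped <- c(dropped, drop)
    feats <- setdiff(feats, drop)
  }
  list(retained = feats, dropped = dropped,
       vifReport = do.call(rbind, report))
}

#' Default hyperparameter grid for the boosted-tree fit
#'
#' Tree count \{100, 300, 500\}, depth \{3, 5, 7\}, learning rate
#' \{0.05, 0.1\}, subsample \{0.8, 1.0\}: a small, standard desk-scale grid.
#'
#' @return Data frame of configurations.
#' @export
defaultXgbGrid <- function() {
  expand.grid(nrounds = c(100L, 300L, 500L), max_depth = c(3L, 5L, 7L),
              eta = c(0.05, 0.1), subsample = c(0.8, 1.0))
}

#' Train the gradient-boosted regression with a seeded grid search
#'
#' Splits the samples at `splitFraction` into training and held-out test
#' sets (seeded random split), selects hyperparameters by k-fold
#' cross-validated RMSE on the training split only, refits the winning
#' configuration on the full training split, and reports R2, MSE, RMSE and
#' MAE on the untouched test split.
#'
#' @param X Feature table (VIF-screened columns only).
#' @param y Numeric target.
#' @param splitFraction Training share (default 0.8).
#' @param grid Hyperparameter grid as from [defaultXgbGrid()]; a single-row
#'   grid skips cross-validation.
#' @param nfold Folds for the grid search (default 5).
#' @param seed Integer seed controlling the split, the fold assignment and
#'   the booster's own subsampling.
#' @return List: `model` (`xgb.Booster`), `metrics` (R2/MSE/RMSE/MAE),
#'   `best` (winning grid row), `trainIdx`, `testIdx`, `features`.
#' @export
trainModel <- function(X, y, splitFraction = 0.8, grid = defaultXgbGrid(),
                       nfold = 5L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (sd(y) <= .Machine$double.eps^0.5) stop("degenerate target variance")
  n <- nrow(X)
  trainIdx <- withSeed(seed, sort(sample.int(n, round(splitFraction * n))))
  testIdx <- setdiff(seq_len(n), trainIdx)
  dtrain <- xgb.DMatrix(X[trainIdx, , drop = FALSE], label = y[trainIdx])

  paramsOf <- function(row) list(objective = "reg:squarederror",
                                 max_depth = row$max_depth, eta = row$eta,
                                 subsample = row$subsample, seed = seed,
                                 nthread = 1L)
  if (nrow(grid) > 1L) {
    cvRmse <- vapply(seq_len(nrow(grid)), function(i) {
      row <- grid[i, ]
      cv <- withSeed(seed, xgb.cv(params = paramsOf(row), data = dtrain,
                                  nrounds = row$nrounds, nfold = nfold,
                                  verbose = 0))
      tail(cv$evaluation_log$test_rmse_mean, 1L)
    }, numeric(1))
    best <- grid[which.min(cvRmse), ]
  } else best <- grid[1L, ]

  model <- xgb.train(params = paramsOf(best), data = dtrain,
                     nrounds = best$nrounds, verbose = 0)
  pred <- predict(model, X[testIdx, , drop = FALSE])
  err <- y[testIdx] - pred
  mse <- mean(err^2)
  metrics <- list(R2 = 1 - sum(err^2) / sum((y[testIdx] - mean(y[testIdx]))^2),
                  MSE = mse, RMSE = sqrt(mse), MAE = mean(abs(err)))
  list(model = model, metrics = metrics, best = best,
       trainIdx = trainIdx, testIdx = testIdx, features = colnames(X))
}

#' Exact SHAP attribution for a fitted booster
#'
#' Per-sample, per-feature tree-path (TreeSHAP) contributions: the base
#' value plus the row sum of attributions reproduces the model prediction
#' (additivity axiom). Feature importance is the mean absolute attribution,
#' normalized to sum to 100.
#'
#' @param model An `xgb.Booster`.
#' @param X Feature table with exactly the model's features, in order.
#' @return List: `shap` (n x p matrix), `baseValue`, `importancePercent`
#'   (named, sums to 100), `ranking` (features by decreasing importance).
#' @export
shapAttribution <- function(model, X) {
  X <- as.matrix(X)
  fn <- xgboost::getinfo(model, "feature_name")
  if (length(fn) && !identical(colnames(X), fn))
    stop("feature mismatch between model and table")
  contrib <- predict(model, X, predcontrib = TRUE)
  p <- ncol(contrib) - 1L
  shap <- contrib[, seq_len(p), drop = FALSE]
  colnames(shap) <- colnames(X)
  imp <- colMeans(abs(shap))
  tot <- sum(imp)
  importancePercent <- if (tot > 0) 100 * imp / tot
                       else rep(100 / p, p)
  names(importancePercent) <- colnames(X)
  list(shap = shap, baseValue = contrib[1L, p + 1L],
       importancePercent = importancePercent,
       ranking = names(sort(importancePercent, decreasing = TRUE)))
}

#' Partial-dependence curve for one feature
#'
#' Traces the model response along a grid spanning the feature's 1st-99th
#' percentile range. In `"at_means"` mode (default) all other features are
#' held at their sample means; `"averaged"` mode averages predictions over
#' the observed rows with the feature forced to each grid value. The two
#' agree for additive models.
#'
#' @param model An `xgb.Booster`.
#' @param X Feature table the model was trained on.
#' @param feature Feature name.
#' @param gridSize Number of grid points (default 50).
#' @param mode `"at_means"` or `"averaged"`.
#' @return Data frame with `grid` and `response`.
#' @export
partialDependence <- function(model, X, feature, gridSize = 50L,
                              mode = c("at_means", "averaged")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  stopifnot(feature %in% colnames(X))
  x <- X[, feature]
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= 0) stop("constant feature: no partial dependence defined")
  grid <- seq(q[1], q[2], length.out = gridSize)
  if (mode == "at_means") {
    nd <- matrix(rep(colMeans(X), each = gridSize), gridSize,
                 dimnames = list(NULL, colnames(X)))
    nd[, feature] <- grid
    resp <- predict(model, nd)
  } else {
    resp <- vapply(grid, function(g) {
      Xi <- X
      Xi[, feature] <- g
      mean(predict(model, Xi))
    }, numeric(1))
  }
  data.frame(grid = grid, response = resp)
}

#' Read thresholds off a partial-dependence curve
#'
#' Fits continuous piecewise-linear models with 0 to `maxBreaks` breaks to
#' the curve, picks the break count by BIC, and returns the break abscissae
#' ordered by the magnitude of the slope change. Breaks closer together
#' than two grid steps are merged (a step in the curve is read as one
#' threshold, not two). Flat and purely linear curves yield an empty list.
#'
#' @param curve Data frame with `grid` and `response` (>= 10 points).
#' @param maxBreaks Maximum breaks considered (default 2).
#' @param minSegment Minimum grid points per segment (default 3).
#' @return Numeric vector of threshold locations (possibly empty).
#' @export
detectThreshold <- function(curve, maxBreaks = 2L, minSegment = 3L) {
  stopifnot(nrow(curve) >= 10L)
  x <- curve$grid
  y <- curve$response
  n <- length(x)
  if (diff(range(y)) <= 1e-12 * max(1, diff(range(x)))) return(numeric(0))
  step <- stats::median(diff(x))

  # scale-aware RSS floor: below this, fits are numerically exact and only
  # the parameter penalty should discriminate (log(RSS) would otherwise
  # amplify round-off differences between exactly fitting models)
  rssFloor <- n * (1e-8 * sd(y))^2
  fitK <- function(breaks) {
    H <- if (length(breaks)) vapply(breaks, function(b) pmax(x - b, 0),
                                    numeric(n)) else NULL
    f <- olsFit(cbind(1, x, H), y)
    if (is.null(f)) return(NULL)
    kp <- 3L + 2L * length(breaks)   # intercept, slope, variance + (change, location) per break
    list(bic = n * log(max(f$rss, rssFloor) / n) + log(n) * kp,
         breaks = breaks, slopeChanges = if (length(breaks)) f$coef[-(1:2)] else numeric(0))
  }

  cand <- list(fitK(numeric(0)))
  interior <- seq.int(minSegment, n - minSegment)
  if (maxBreaks >= 1L)
    for (i in interior) cand[[length(cand) + 1L]] <- fitK(x[i])
  # the middle segment of a two-break fit may be short: a steep transition
  # between plateaus is exactly the threshold phenomenon being read out
  if (maxBreaks >= 2L)
    for (i in interior) for (j in interior[interior > i])
      cand[[length(cand) + 1L]] <- fitK(c(x[i], x[j]))
  cand <- Filter(Negate(is.null), cand)
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "bic"))]]
  if (!length(best$breaks)) return(numeric(0))

  ord <- order(abs(best$slopeChanges), decreasing = TRUE)
  br <- best$breaks[ord]
  sc <- abs(best$slopeChanges)[ord]
  # merge breaks within two grid steps: one physical threshold
  out <- numeric(0)
  used <- rep(FALSE, length(br))
  for (i in seq_along(br)) {
    if (used[i]) next
    close <- which(!used & abs(br - br[i]) <= 2 * step)
    out <- c(out, sum(br[close] * sc[close]) / sum(sc[close]))
    used[close] <- TRUE
  }
  out
}

#' Run the full driver-analysis chain on one feature table
#'
#' VIF screening, seeded grid-search boosting, SHAP attribution, partial
#' dependence for the top `nPdp` features, and threshold detection on each
#' curve.
#'
#' @param features Data frame of candidate features.
#' @param target Numeric response (e.g. annual VI paired pixel-years).
#' @param vifCutoff VIF exclusion threshold (default 10).
#' @param splitFraction,grid,nfold,seed Passed to [trainModel()].
#' @param nPdp Number of top-importance features to trace (default 4).
#' @param pdpMode Passed to [partialDependence()].
#' @param maxBreaks Passed to [detectThreshold()].
#' @return A [DriverAnalysis-class].
#' @export
analyzeDrivers <- function(features, target, vifCutoff = 10,
                           splitFraction = 0.8, grid = defaultXgbGrid(),
                           nfold = 5L, seed = 1L, nPdp = 4L,
                           pdpMode = c("at_means", "averaged"),
                           maxBreaks = 2L) {
  pdpMode <- match.arg(pdpMode)
  scr <- vifScreen(features, cutoff = vifCutoff)
  Xr <- as.matrix(features[, scr$retained, drop = FALSE])
  fit <- trainModel(Xr, target, splitFraction = splitFraction, grid = grid,
                    nfold = nfold, seed = seed)
  sh <- shapAttribution(fit$model, Xr)
  top <- utils::head(sh$ranking, nPdp)
  curves <- lapply(top, function(f)
    partialDependence(fit$model, Xr, f, mode = pdpMode))
  names(curves) <- top
  thr <- lapply(curves, detectThreshold, maxBreaks = maxBreaks)
  new("DriverAnalysis", retainedFeatures = scr$retained,
      vifReport = scr$vifReport, model = fit$model, metrics = fit$metrics,
      importancePercent = sh$importancePercent, shapMatrix = sh$shap,
      baseValue = sh$baseValue, pdpCurves = curves, thresholds = thr,
      skipped = FALSE)
}

#' Per-ecosystem driver analysis
#'
#' Runs [analyzeDrivers()] independently for each ecosystem class; retained
#' features may differ between classes. Classes with fewer than
#' `minSamples` rows are reported with a skip flag and a warning.
#'
#' @param tables Named list; each element a list with `features` and
#'   `target`.
#' @param minSamples Minimum rows per class (default 500).
#' @param ... Passed to [analyzeDrivers()].
#' @return Named list of [DriverAnalysis-class] objects.
#' @export
perEcosystemAnalysis <- function(tables, minSamples = 500L, ...) {
  out <- lapply(names(tables), function(cl) {
    tb <- tables[[cl]]
    if (nrow(tb$features) < minSamples) {
      warning("class '", cl, "' has fewer than ", minSamples,
              " samples; skipped")
      return(new("DriverAnalysis", retainedFeatures = character(0),
                 vifReport = data.frame(), model = NULL, metrics = list(),
                 importancePercent = numeric(0),
                 shapMatrix = matrix(numeric(0), 0, 0), baseValue = NA_real_,
                 pdpCurves = list(), thresholds = list(), skipped = TRUE))
    }
    analyzeDrivers(tb$features, tb$target, ...)
  })
  names(out) <- names(tables)
  out
}
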
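test_that("VIF screening drops collinear features iteratively and is idempotent", {
  set.seed(51)
  n <- 600
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  scr <- vifScreen(X)
  expect_equal(scr$retained, c("a", "b", "c"))
  expect_true(all(scr$vifReport$vif < 1.1))

  # duplicated feature: exactly one of the pair dropped
  X$d <- X$a
  scr <- vifScreen(X)
  expect_length(intersect(c("a", "d"), scr$retained), 1)
  expect_length(scr$dropped, 1)

  # planted r = 0.999 pair, independent lm-based VIF oracle on the retained set
  dt <- generateDriverTable(
    driverSpec(collinearPairs = list(list(a = "TMX", b = "TEM", r = 0.999))),
    1000, seed = 4)
  scr <- vifScreen(dt$features)
  expect_length(intersect(c("TMX", "TEM"), scr$retained), 1)
  for (f in scr$retained) {
    r2 <- summary(lm(reformulate(setdiff(scr$retained, f), f),
                     data = dt$features))$r.squared
    expect_lt(1 / (1 - r2), 10)
  }

  # idempotence: screening the retained set removes nothing
  scr2 <- vifScreen(dt$features[, scr$retained])
  expect_identical(scr2$retained, scr$retained)
  expect_length(scr2$dropped, 0)
})

test_that("model training reports honest held-out metrics", {
  set.seed(52)
  n <- 1500
  X <- cbind(x1 = runif(n, 0, 10), x2 = runif(n))
  fit <- trainModel(X, sin(X[, "x1"]), grid = fastGrid(), seed = 1)
  expect_gte(fit$metrics$R2, 0.99)

  noise <- trainModel(X, rnorm(n), grid = fastGrid(), seed = 1)
  expect_lte(noise$metrics$R2, 0.1)

  expect_equal(fit$metrics$RMSE, sqrt(fit$metrics$MSE), tolerance = 1e-10)
  expect_equal(length(fit$trainIdx), round(0.8 * n))
  expect_length(intersect(fit$trainIdx, fit$testIdx), 0)

  expect_error(trainModel(X, rep(1, n), grid = fastGrid()), "degenerate")
})

test_that("planted mixed effects are learnable at 10:1 signal-to-noise", {
  dt <- generateDriverTable(driverSpec(), 3000, seed = 6)
  scr <- vifScreen(dt$features)
  fit <- trainModel(as.matrix(dt$features[, scr$retained]), dt$target,
                    grid = fastGrid(), seed = 2)
  expect_gte(fit$metrics$R2, 0.8)
})

test_that("SHAP attributions are additive and proportional to planted effects", {
  set.seed(53)
  n <- 1500
  X <- cbind(a = runif(n), b = runif(n), flat = runif(n))
  y <- 3 * X[, "a"] + 1 * X[, "b"] + rnorm(n, 0, 0.05)
  fit <- trainModel(X, y, grid = fastGrid(), seed = 5)
  sh <- shapAttribution(fit$model, X)

  pred <- predict(fit$model, X)
  expect_lt(max(abs(sh$baseValue + rowSums(sh$shap) - pred)), 1e-4)
  expect_equal(sum(sh$importancePercent), 100, tolerance = 1e-6)

  # a never-informative feature gets ~no credit
  expect_lt(sh$importancePercent[["flat"]], 3)

  # 3:1 planted effect ratio on orthogonal uniforms
  ratio <- sh$importancePercent[["a"]] / sh$importancePercent[["b"]]
  expect_gt(ratio, 2); expect_lt(ratio, 4.5)

  # permuting feature columns permutes the importances
  Xp <- X[, c("flat", "a", "b")]
  shp <- shapAttribution(trainModel(Xp, y, grid = fastGrid(), seed = 5)$model, Xp)
  expect_equal(shp$importancePercent[colnames(X)], sh$importancePercent,
               tolerance = 0.05)

  expect_error(shapAttribution(fit$model, Xp), "mismatch")
})

test_that("partial dependence traces the model response along one feature", {
  set.seed(54)
  n <- 2000
  X <- cbind(x = runif(n, 0, 10), z = runif(n))
  # single learned split: step response at x = 5
  stepFit <- trainModel(X, as.numeric(X[, "x"] > 5), grid = fastGrid(), seed = 1)
  pd <- partialDependence(stepFit$model, X, "x")
  expect_lt(mean(pd$response[pd$grid < 4.5]), 0.1)
  expect_gt(mean(pd$response[pd$grid > 5.5]), 0.9)

  # additive truth f(x) = x: interior slope ~ 1 and modes agree
  linFit <- trainModel(X, X[, "x"] + rnorm(n, 0, 0.05), grid = fastGrid(), seed = 1)
  pdA <- partialDependence(linFit$model, X, "x", mode = "at_means")
  pdB <- partialDependence(linFit$model, X, "x", mode = "averaged")
  interior <- pdA$grid > 1 & pdA$grid < 9
  slope <- coef(lm(pdA$response[interior] ~ pdA$grid[interior]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
  expect_lt(max(abs(pdA$response - pdB$response)), 0.05 * sd(X[, "x"]))

  expect_error(partialDependence(linFit$model, cbind(x = rep(1, 10), z = 1:10), "x"),
               "constant")
})

test_that("threshold detection reads breaks off a curve by BIC", {
  grid <- seq(40, 120, length.out = 50)
  stepCurve <- data.frame(grid = grid, response = ifelse(grid < 79, 1, 0))
  th <- detectThreshold(stepCurve)
  expect_length(th, 1)
  expect_lt(abs(th - 79), diff(grid)[1] + 1e-9)

  linCurve <- data.frame(grid = grid, response = 0.3 * grid)
  expect_length(detectThreshold(linCurve), 0)

  flatCurve <- data.frame(grid = grid, response = rep(2, 50))
  expect_length(detectThreshold(flatCurve), 0)

  # plateau: slope change (not a jump) at the planted knee
  knee <- data.frame(grid = grid, response = -0.02 * (pmin(grid, 79) - 79))
  th <- detectThreshold(knee)
  expect_length(th, 1)
  expect_lt(abs(th - 79), 2 * diff(grid)[1])
})

test_that("per-ecosystem analysis runs the chain per class and flags skips", {
  dt <- generateDriverTable(driverSpec(), 1200, seed = 8)
  tables <- list(grassland = dt, forest = dt,
                 wetland = list(features = dt$features[1:50, ],
                                target = dt$target[1:50]))
  expect_warning(res <- perEcosystemAnalysis(tables, grid = fastGrid(), seed = 3),
                 "skipped")
  expect_true(res$wetland@skipped)
  expect_false(res$grassland@skipped)
  # identical inputs give identical outputs
  expect_identical(importancePercent(res$grassland), importancePercent(res$forest))
  expect_identical(thresholds(res$grassland), thresholds(res$forest))
})

test_that("class-specific planted drivers surface as the top importance", {
  base <- driverSpec(collinearPairs = list(), responseShapes = list(),
                     noiseSd = 1)
  wet <- driverSpec(collinearPairs = list(),
                    responseShapes = list(
                      NTL = list(shape = "step", threshold = 1.5, low = 0, high = 2)))
  hits <- sum(sapply(1:3, function(s) {
    tab <- generateDriverTable(wet, 1500, seed = s)
    da <- analyzeDrivers(tab$features, tab$target, grid = fastGrid(), seed = s)
    names(sort(importancePercent(da), decreasing = TRUE))[1] == "NTL"
  }))
  expect_gte(hits, 2)
  # and a flat table has no dominant driver
  tabF <- generateDriverTable(base, 1500, seed = 1)
  daF <- analyzeDrivers(tabF$features, tabF$target, grid = fastGrid(), seed = 1)
  expect_lt(max(importancePercent(daF)), 40)
})
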
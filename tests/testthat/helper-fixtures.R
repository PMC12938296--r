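# Shared fixtures: everything is generated in code at test time.

# single-configuration grid: skips cross-validation, keeps unit tests fast
fastGrid <- function()
  data.frame(nrounds = 150L, max_depth = 4L, eta = 0.1, subsample = 1.0)

# two-configuration grid exercising the CV grid search
cvGrid <- function()
  expand.grid(nrounds = 150L, max_depth = c(3L, 5L), eta = 0.1, subsample = 1.0)

# small cube with known coefficients
tinyCube <- function(nRows = 5, nCols = 5, years = 1983:1992, seed = 1,
                     params = processParams()) {
  generateClimateVeg(landscapeSpec(nRows, nCols, years = years, seed = seed),
                     params)
}

cubeTruth <- function(cube) S4Vectors::metadata(cube)$truth
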
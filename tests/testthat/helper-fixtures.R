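# Shared fixtures, built in code. The trained models are expensive enough to
# cache per test run.

fx <- new.env(parent = emptyenv())

# noise-free compensation model on the default 10-level calibration series
fixtureCompModel <- function() {
  if (is.null(fx$comp)) {
    cal <- makeChloramineCalibration(noiseSd = 0)
    fx$comp <- fitCompensation(computePairwiseDeltas(cal$spectra, cal$levels))
  }
  fx$comp
}

# NOx regressor trained on the noise-free training set with a reduced grid
# (the full default grid is exercised in the acceptance tests)
fixtureRegressor <- function() {
  if (is.null(fx$reg)) {
    ts <- makeNoxTrainingSet(noiseSd = 0, seed = 1)
    fx$reg <- gridSearchTrain(ts$spectra, ts$labels, cGrid = c(10, 1000),
                              gammaGrid = c(0.001, 0.1), seed = 1)
  }
  fx$reg
}

# small deterministic spectrum for I/O tests
rampSpectrum <- function(grid = defaultGrid()) {
  spectrum(grid, wavelengths(grid) / 1000, timestamp = "2021-06-01T00:00:00",
           label = "ramp")
}
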
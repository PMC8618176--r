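# The 245 nm-anchored per-wavelength linear decay compensation and NOx
# spectrum isolation.

test_that("pairwise deltas enumerate C(n,2) oriented records", {
  mk <- function(n) makeChloramineCalibration(levels = seq(0.5, 4, length.out = n),
                                              noiseSd = 0)
  cal3 <- mk(3)
  d3 <- computePairwiseDeltas(cal3$spectra, cal3$levels)
  expect_length(d3@anchor, 3L)
  cal10 <- mk(10)
  d10 <- computePairwiseDeltas(cal10$spectra, cal10$levels)
  expect_length(d10@anchor, 45L)
  expect_true(all(d10@anchor >= 0))
  expect_equal(ncol(d10@deltas), 90L)
  expect_equal(d10@modelledWavelengths, seq(200, 244.5, by = 0.5))
  # baseline-only pairing gives n - 1 records
  db <- computePairwiseDeltas(cal10$spectra, cal10$levels, pairs = "baseline")
  expect_length(db@anchor, 9L)
  expect_error(computePairwiseDeltas(cal3$spectra[1:2]), "insufficient")
})

test_that("identical spectra produce an all-zero pair record", {
  s <- composeSpectrum(mixtureState(cNH2Cl = 2))
  cal <- list(s, s, composeSpectrum(mixtureState(cNH2Cl = 3)))
  d <- computePairwiseDeltas(cal)
  expect_equal(d@anchor[1], 0)
  expect_equal(max(abs(d@deltas[1, ])), 0)
})

test_that("noise-free records obey the Beer-Lambert absorptivity ratio", {
  cal <- makeChloramineCalibration(noiseSd = 0)
  d <- computePairwiseDeltas(cal$spectra, cal$levels)
  ratio <- vapply(d@modelledWavelengths,
                  function(l) epsilonAt("monochloramine", l) /
                    epsilonAt("monochloramine", 245), numeric(1))
  for (r in seq_along(d@anchor))
    expect_equal(d@deltas[r, ] / d@anchor[r], ratio,
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("compensation fit recovers exact lines and flags degeneracy", {
  # records generated as delta_i = 0.4 * delta_245 exactly
  anchor <- c(0.1, 0.2, 0.4, 0.7)
  dset <- new("DeltaDataset", anchorNm = 245, anchor = anchor,
              deltas = cbind(a = 0.4 * anchor), modelledWavelengths = 220,
              concRange = c(NA_real_, NA_real_))
  m <- fitCompensation(dset)
  expect_equal(m@slope, 0.4, tolerance = 1e-12)
  expect_equal(m@intercept, 0, tolerance = 1e-12)
  expect_equal(m@r2, 1, tolerance = 1e-12)
  expect_equal(m@rmse, 0, tolerance = 1e-12)
  degen <- new("DeltaDataset", anchorNm = 245, anchor = rep(0.2, 4),
               deltas = cbind(a = rep(0.08, 4)), modelledWavelengths = 220,
               concRange = c(NA_real_, NA_real_))
  expect_error(fitCompensation(degen), "rank deficiency")
})

test_that("noise-free calibration gives absorptivity-ratio slopes and zero intercepts", {
  m <- fixtureCompModel()
  truth <- vapply(m@wavelengthsNm,
                  function(l) epsilonAt("monochloramine", l) /
                    epsilonAt("monochloramine", 245), numeric(1))
  expect_lt(max(abs(m@slope - truth)), 1e-9)
  expect_lt(max(abs(m@intercept)), 1e-9)
})

test_that("fit quality improves toward the anchor under flat noise", {
  cal <- makeChloramineCalibration(noiseSd = 0.001, seed = 21)
  m <- fitCompensation(computePairwiseDeltas(cal$spectra, cal$levels))
  wl <- m@wavelengthsNm
  expect_gte(mean(m@r2[wl >= 240]), mean(m@r2[wl <= 204.5]))
})

test_that("predictDeltas is linear and refuses negative anchors gracefully", {
  m <- fixtureCompModel()
  # intercepts are ~0 on the clean fixture
  expect_lt(max(abs(predictDeltas(m, 0))), 1e-9)
  expect_equal(predictDeltas(m, 0.2), 2 * predictDeltas(m, 0.1),
               tolerance = 1e-6)
  expect_warning(z <- predictDeltas(m, -0.01), "negative anchor")
  expect_equal(unname(z), rep(0, 90))
})

test_that("held-out pair deltas are predicted within 1e-6 AU", {
  cal <- makeChloramineCalibration(noiseSd = 0)
  m <- fitCompensation(computePairwiseDeltas(cal$spectra[1:8],
                                             cal$levels[1:8]))
  held <- subtractSpectra(cal$spectra[[10]], cal$spectra[[9]])
  pred <- predictDeltas(m, deltaAt(held, 245))
  truth <- vapply(m@wavelengthsNm, function(l) deltaAt(held, l), numeric(1))
  expect_lt(max(abs(pred - truth)), 1e-6)
})

test_that("decay estimate and isolation satisfy the algebraic identities", {
  base <- composeSpectrum(mixtureState(cNH2Cl = 2, cDOC = 2.4),
                          label = "baseline")
  m <- fixtureCompModel()
  # all-zero deltas and anchor: baseline returned unchanged
  est0 <- estimateDecaySpectrum(base, rep(0, 90), 0)
  expect_equal(absorbance(est0), absorbance(base))
  # positive deltas: estimate <= baseline pointwise on the modelled grid
  deltas <- predictDeltas(m, 0.05)
  est <- estimateDecaySpectrum(base, deltas, 0.05)
  wl <- wavelengths(base)
  mg <- wl <= 244.5
  expect_true(all(absorbance(est)[mg] <= absorbance(base)[mg] + 1e-12))
  # sample equal to the estimate isolates to zero
  nox0 <- isolateNox(est, est)
  expect_equal(absorbance(nox0), rep(0, 201))
  # end-to-end identity: NOx = S_t - S_0 + predicted deltas on the modelled grid
  st <- composeSpectrum(mixtureState(cNH2Cl = 1.6, cDOC = 2.4, cNO2N = 0.1),
                        label = "sample")
  nox <- isolateNox(st, est)
  expect_equal(absorbance(nox)[mg],
               (absorbance(st) - absorbance(base))[mg] + unname(deltas),
               tolerance = 1e-12)
  expect_error(isolateNox(alignToGrid(st, wavelengthGrid(200, 250, 0.5)), est),
               "grid mismatch")
})

test_that("zero decay reduces isolation to the plain baseline difference", {
  base <- composeSpectrum(mixtureState(cDOC = 2.4))
  st <- composeSpectrum(mixtureState(cDOC = 2.4, cNO2N = 0.2, cNO3N = 0.1))
  m <- fixtureCompModel()
  dA <- deltaAt(subtractSpectra(base, st), 245)
  expect_equal(dA, 0, tolerance = 1e-12)
  est <- estimateDecaySpectrum(base, predictDeltas(m, dA), dA)
  nox <- isolateNox(st, est)
  expect_equal(absorbance(nox), absorbance(st) - absorbance(base),
               tolerance = 1e-9)
})

test_that("monochloramine-only series isolates to nothing", {
  m <- fixtureCompModel()
  sim <- simulateDecaySeries(decayOnlyScenario())
  base <- sim$spectra[[1]]
  wl <- wavelengths(base)
  for (s in sim$spectra[-1]) {
    dA <- deltaAt(subtractSpectra(base, s), 245)
    est <- estimateDecaySpectrum(base, predictDeltas(m, dA), dA)
    # the estimate reproduces the observed spectrum on the modelled grid
    expect_lt(max(abs((absorbance(est) - absorbance(s))[wl <= 245])), 1e-9)
    expect_lt(max(abs(absorbance(isolateNox(s, est))[wl <= 245])), 1e-9)
  }
})

test_that("nitrifying series isolates the injected NOx component", {
  m <- fixtureCompModel()
  sim <- simulateDecaySeries(nitrifyingScenario())
  base <- sim$spectra[[1]]
  wl <- wavelengths(base)
  keep <- wl >= 200 & wl <= 240
  last <- length(sim$spectra)
  s <- sim$spectra[[last]]
  stt <- sim$states[[last]]
  dA <- deltaAt(subtractSpectra(base, s), 245)
  nox <- isolateNox(s, estimateDecaySpectrum(base, predictDeltas(m, dA), dA))
  injected <- absorbance(composeSpectrum(mixtureState(cNO2N = stt@cNO2N,
                                                      cNO3N = stt@cNO3N)))
  expect_lt(max(abs(absorbance(nox)[keep] - injected[keep])), 1e-9)
  # clipped variant is nonnegative and untouched where positive
  noxc <- isolateNox(s, estimateDecaySpectrum(base, predictDeltas(m, dA), dA),
                     clip = TRUE)
  expect_true(all(absorbance(noxc) >= 0))
})

test_that("compensation model JSON round-trips exactly", {
  m <- fixtureCompModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeCompensationModel(m, path)
  m2 <- readCompensationModel(path)
  expect_equal(m2@slope, m@slope, tolerance = 1e-15)
  expect_equal(m2@intercept, m@intercept, tolerance = 1e-15)
  expect_equal(m2@r2, m@r2, tolerance = 1e-15)
  expect_equal(m2@wavelengthsNm, m@wavelengthsNm)
  expect_equal(m2@nRecords, m@nRecords)
})
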
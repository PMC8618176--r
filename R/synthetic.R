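# Synthetic Beer-Lambert spectra: component bands, mixtures, and
# chloramine-decay / nitrification time courses with known ground truth.
#
# Band shapes are parametric (Gaussian bands for the chemical species, an
# exponential continuum for NOM) with positions and orderings fixed by the
# spectroscopy of these species: monochloramine peaks at 245 nm, nitrite at
# 210 nm (secondary 355 nm), nitrate at 205 nm (secondary 302 nm; the primary
# band is right-skewed, so a saturated band reads as a peak shifted to longer
# wavelengths), NOM decreases monotonically with wavelength. The nitrite and
# nitrate bands are compact-support (pedestal-subtracted Gaussians, zero
# beyond 4 sigma): these species have no meaningful absorbance at 245 nm,
# which is precisely why the 245 nm offset can anchor the decay compensation.
# Absolute absorptivities are free parameters chosen to give realistic AU
# magnitudes in a 10 cm cell; see the package vignette.

.BANDS <- list(
  monochloramine = list(
    # eps(245) ~ molar absorptivity 445 M-1 cm-1 / 51.48 g/mol
    primary = c(center = 245, sigmaL = 20, sigmaR = 20, amp = 0.0086,
                cut = Inf)),
  nitrite_N = list(
    primary = c(center = 210, sigmaL = 8.5, sigmaR = 8.5, amp = 0.20, cut = 4),
    secondary = c(center = 355, sigmaL = 18, sigmaR = 18, amp = 0.0020,
                  cut = 4)),
  nitrate_N = list(
    # right-skewed primary band: sigma 7 nm on the blue side, 9.5 on the red
    primary = c(center = 205, sigmaL = 7, sigmaR = 9.5, amp = 0.28, cut = 4),
    secondary = c(center = 302, sigmaL = 14, sigmaR = 14, amp = 0.0015,
                  cut = 4)),
  NOM = list(exponential = c(amp = 0.045, k = 0.015, ref = 200)))

.asymGauss <- function(wl, p) {
  sigma <- ifelse(wl < p["center"], p["sigmaL"], p["sigmaR"])
  z2 <- (wl - p["center"])^2 / (2 * sigma^2)
  g <- exp(-z2)
  if (is.finite(p["cut"])) {
    # subtract the pedestal and rescale so the band reaches zero smoothly at
    # the cut and stays zero beyond it
    g0 <- exp(-p["cut"]^2 / 2)
    g <- pmax(0, (g - g0) / (1 - g0))
  }
  unname(p["amp"]) * g
}

#' Absorptivity curve of one spectral component
#'
#' Deterministic parametric extinction curve per unit concentration per cm
#' path: AU/(mg/L)/cm for monochloramine, AU/(mg-N/L)/cm for nitrite_N and
#' nitrate_N, AU/(mg-C/L)/cm for NOM.
#'
#' @param species one of \code{"monochloramine"}, \code{"nitrite_N"},
#'   \code{"nitrate_N"}, \code{"NOM"}
#' @param grid a \code{WavelengthGrid}
#' @return an \code{ExtinctionCurve}
#' @examples
#' crv <- componentCurve("monochloramine", defaultGrid())
#' peakWavelength(crv)  # 245 nm
#' @export
componentCurve <- function(species, grid = defaultGrid()) {
  if (!species %in% names(.BANDS))
    .stopValidation("unknown species '", species, "'; expected one of: ",
                    paste(names(.BANDS), collapse = ", "))
  wl <- wavelengths(grid)
  bands <- .BANDS[[species]]
  if (species == "NOM") {
    p <- bands$exponential
    eps <- p["amp"] * exp(-p["k"] * (wl - p["ref"]))
  } else {
    eps <- rowSums(vapply(bands, function(p) .asymGauss(wl, p),
                          numeric(length(wl))))
  }
  new("ExtinctionCurve", species = species, grid = grid,
      epsilon = as.numeric(eps))
}

#' Absorptivity of one species at one wavelength
#'
#' Closed-form evaluation of the component band model, convenient as an
#' oracle for Beer-Lambert identities.
#'
#' @param species component name as in \code{\link{componentCurve}}
#' @param wavelength nm
#' @return absorptivity (AU per unit concentration per cm)
#' @export
epsilonAt <- function(species, wavelength) {
  if (!species %in% names(.BANDS)) .stopValidation("unknown species: ", species)
  bands <- .BANDS[[species]]
  if (species == "NOM") {
    p <- bands$exponential
    return(as.numeric(p["amp"] * exp(-p["k"] * (wavelength - p["ref"]))))
  }
  sum(vapply(bands, function(p) as.numeric(.asymGauss(wavelength, p)),
             numeric(1)))
}

#' Compose a mixture spectrum under Beer-Lambert additivity
#'
#' A(lambda) = pathlength * sum over species of eps(lambda) * c, plus optional
#' Gaussian instrument noise, then clipped at a detector saturation ceiling
#' when one is given. Ammonia contributes no absorbance. Seeded noise is
#' reproducible.
#'
#' @param state a \code{MixtureState}
#' @param grid a \code{WavelengthGrid}
#' @param pathlengthCm optical path in cm
#' @param noiseSd Gaussian noise standard deviation (AU), >= 0
#' @param saturationAU optional absorbance ceiling (detector saturation)
#' @param seed optional RNG seed for the noise
#' @param timestamp,label metadata passed to the \code{Spectrum}
#' @return a \code{Spectrum}
#' @export
composeSpectrum <- function(state, grid = defaultGrid(), pathlengthCm = 10,
                            noiseSd = 0, saturationAU = NULL, seed = NULL,
                            timestamp = "", label = "") {
  validObject(state)
  if (noiseSd < 0) .stopValidation("noiseSd must be >= 0")
  wl <- wavelengths(grid)
  a <- pathlengthCm * (
    state@cNH2Cl * componentCurve("monochloramine", grid)@epsilon +
    state@cNO2N  * componentCurve("nitrite_N", grid)@epsilon +
    state@cNO3N  * componentCurve("nitrate_N", grid)@epsilon +
    state@cDOC   * componentCurve("NOM", grid)@epsilon)
  if (noiseSd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    a <- a + stats::rnorm(length(wl), 0, noiseSd)
  }
  if (!is.null(saturationAU)) a <- pmin(a, saturationAU)
  spectrum(grid, a, pathlengthCm = pathlengthCm, timestamp = timestamp,
           label = label)
}

#' Ground-truth mixture states along a decay scenario
#'
#' Deterministic chemistry bookkeeping of \code{\link{simulateDecaySeries}}:
#' first-order monochloramine decay, ammonia release at a fixed yield,
#' logistic ammonia-to-NOx conversion after onset, linear DOC drift.
#' Nitrogen is conserved: released + initial ammonia-N equals converted
#' NOx-N plus remaining free ammonia-N.
#'
#' @param scenario a \code{DecayScenario}
#' @param times evaluation times (days)
#' @return list of \code{MixtureState}, one per time
#' @export
scenarioStates <- function(scenario, times = scenario@sampleTimes) {
  ini <- scenario@initial
  lapply(times, function(t) {
    cNH2Cl <- ini@cNH2Cl * exp(-scenario@kDecay * t)
    releasedN <- scenario@ammoniaYield * (ini@cNH2Cl - cNH2Cl)
    availN <- ini@cNH3N + releasedN
    dt <- t - scenario@nitrificationOnset
    phi <- if (dt > 0 && scenario@nitrificationRate > 0)
      tanh(scenario@nitrificationRate * dt / 2) else 0
    noxN <- phi * availN
    cDOC <- max(0, ini@cDOC - scenario@docDrift * t / scenario@horizonDays)
    mixtureState(cNH2Cl = cNH2Cl,
                 cNO2N = ini@cNO2N + scenario@nitriteFraction * noxN,
                 cNO3N = ini@cNO3N + (1 - scenario@nitriteFraction) * noxN,
                 cNH3N = (1 - phi) * availN,
                 cDOC = cDOC)
  })
}

#' Simulate a chloramine-decay / nitrification spectra series
#'
#' One spectrum per sample time via \code{\link{composeSpectrum}}, with the
#' matching ground-truth \code{MixtureState}s. The same seed gives a
#' bit-identical series.
#'
#' @param scenario a \code{DecayScenario}
#' @param grid a \code{WavelengthGrid}
#' @param pathlengthCm optical path in cm
#' @return list with elements \code{spectra} (list of \code{Spectrum}),
#'   \code{states} (list of \code{MixtureState}) and \code{times} (days)
#' @export
simulateDecaySeries <- function(scenario, grid = defaultGrid(),
                                pathlengthCm = 10) {
  validObject(scenario)
  if (!length(scenario@sampleTimes)) .stopValidation("empty sample_times")
  states <- scenarioStates(scenario)
  spectra <- lapply(seq_along(scenario@sampleTimes), function(i) {
    composeSpectrum(states[[i]], grid, pathlengthCm,
                    noiseSd = scenario@noiseSd,
                    seed = if (scenario@noiseSd > 0)
                      scenario@seed + i else NULL,
                    timestamp = sprintf("day%05.1f", scenario@sampleTimes[i]),
                    label = sprintf("day%05.1f", scenario@sampleTimes[i]))
  })
  list(spectra = spectra, states = states, times = scenario@sampleTimes)
}

#' Ground-truth table of a simulated series
#'
#' @param states list of \code{MixtureState}
#' @param times sampling times (days)
#' @return data.frame with time and all component concentrations, plus the
#'   combined NOx-N column
#' @export
groundTruthFrame <- function(states, times) {
  data.frame(
    time_days = times,
    nh2cl_mg_L = vapply(states, function(s) s@cNH2Cl, numeric(1)),
    no2_mgN_L = vapply(states, function(s) s@cNO2N, numeric(1)),
    no3_mgN_L = vapply(states, function(s) s@cNO3N, numeric(1)),
    nh3_mgN_L = vapply(states, function(s) s@cNH3N, numeric(1)),
    doc_mgC_L = vapply(states, function(s) s@cDOC, numeric(1)),
    nox_mgN_L = vapply(states, function(s) s@cNO2N + s@cNO3N, numeric(1)))
}

.MOLAR_MASS <- c(K = 39.098, N = 14.007, O = 15.999, Na = 22.990)

#' Mass of salt needed for a nitrogen-basis standard solution
#'
#' Grams of dry salt to dissolve for a target concentration expressed as
#' nitrogen (mg-N/L). For example 100 mg-N/L of nitrate in 1 L requires
#' 0.7218 g KNO3.
#'
#' @param compound \code{"KNO3"} or \code{"NaNO2"}
#' @param targetMgNPerL target concentration, mg-N/L
#' @param volumeL solution volume, L
#' @return mass in grams
#' @examples
#' standardSolutionMass("KNO3", 100, 1)   # 0.7218 g
#' standardSolutionMass("NaNO2", 100, 1)  # 0.4926 g
#' @export
standardSolutionMass <- function(compound, targetMgNPerL, volumeL) {
  if (targetMgNPerL < 0) .stopValidation("target concentration must be >= 0")
  if (volumeL <= 0) .stopValidation("volume must be > 0")
  m <- .MOLAR_MASS
  molar <- switch(compound,
                  KNO3 = m["K"] + m["N"] + 3 * m["O"],
                  NaNO2 = m["Na"] + m["N"] + 2 * m["O"],
                  .stopValidation("unknown compound '", compound,
                                  "'; expected KNO3 or NaNO2"))
  as.numeric(targetMgNPerL * volumeL * molar / m["N"]) / 1000
}

#' Pure-monochloramine calibration series
#'
#' Spectra of monochloramine in ultrapure water at a range of concentrations,
#' as used to fit the decay-compensation model. Default levels span the
#' chloramination practice range 0.2--5 mg/L.
#'
#' @param levels monochloramine concentrations, mg/L, increasing
#' @param grid a \code{WavelengthGrid}
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @param pathlengthCm optical path in cm
#' @return list with \code{spectra} (labelled by concentration) and
#'   \code{levels}
#' @export
makeChloramineCalibration <- function(levels = seq(0.2, 5, length.out = 10),
                                      grid = defaultGrid(), noiseSd = 0,
                                      seed = 1, pathlengthCm = 10) {
  if (any(levels < 0)) .stopValidation("concentrations must be >= 0")
  if (is.unsorted(levels, strictly = TRUE))
    .stopValidation("levels must be strictly increasing")
  spectra <- lapply(seq_along(levels), function(i) {
    composeSpectrum(mixtureState(cNH2Cl = levels[i]), grid, pathlengthCm,
                    noiseSd = noiseSd,
                    seed = if (noiseSd > 0) seed + i else NULL,
                    label = format(levels[i]))
  })
  list(spectra = spectra, levels = levels)
}

#' Synthetic nitrate/nitrite training set for the NOx regression
#'
#' Cartesian combinations of nitrite and nitrate standards composed with only
#' those two components (an isolated NOx spectrum contains no NOM or
#' monochloramine signal). Labels are the combined concentration
#' c(NO2-N) + c(NO3-N); with the default levels the largest label is
#' 2.4 mg-N/L, the regression's working ceiling.
#'
#' @param grid a \code{WavelengthGrid}
#' @param nitriteLevels,nitrateLevels standard concentrations, mg-N/L,
#'   within 0--1.2 each by default
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @param pathlengthCm optical path in cm
#' @return list with \code{spectra}, \code{labels} (combined mg-N/L),
#'   \code{nitrite} and \code{nitrate} (per-sample truth)
#' @export
makeNoxTrainingSet <- function(grid = defaultGrid(),
                               nitriteLevels = c(0, 0.001, 0.005, 0.01, 0.05,
                                                 0.1, 0.3, 0.6, 0.9, 1.2),
                               nitrateLevels = nitriteLevels,
                               noiseSd = 0.001, seed = 1, pathlengthCm = 10) {
  if (any(nitriteLevels < 0) || any(nitrateLevels < 0))
    .stopValidation("standard concentrations must be >= 0")
  combos <- expand.grid(no2 = nitriteLevels, no3 = nitrateLevels)
  spectra <- lapply(seq_len(nrow(combos)), function(i) {
    composeSpectrum(mixtureState(cNO2N = combos$no2[i], cNO3N = combos$no3[i]),
                    grid, pathlengthCm, noiseSd = noiseSd,
                    seed = if (noiseSd > 0) seed + i else NULL,
                    label = sprintf("no2=%g,no3=%g", combos$no2[i], combos$no3[i]))
  })
  list(spectra = spectra, labels = combos$no2 + combos$no3,
       nitrite = combos$no2, nitrate = combos$no3)
}

#' Preset nitrifying scenario
#'
#' A distribution-system sample with a low monochloramine residual
#' (1.3 mg/L) and moderate free ammonia, sampled weekly over eight weeks:
#' the residual decays first-order, nitrification starts after a one-week
#' lag, and the converted NOx-N climbs to roughly 0.5 mg-N/L by the end of
#' the horizon. Noise-free by default, for pipeline validation against
#' exact ground truth.
#'
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @return a \code{DecayScenario}
#' @export
nitrifyingScenario <- function(noiseSd = 0, seed = 1) {
  decayScenario(
    initial = mixtureState(cNH2Cl = 1.3, cNH3N = 0.40, cDOC = 2.5),
    kDecay = 0.08, nitrificationOnset = 7, nitrificationRate = 0.05,
    nitriteFraction = 0.5, ammoniaYield = 0.25, docDrift = 0,
    horizonDays = 56, sampleTimes = seq(0, 56, by = 7),
    noiseSd = noiseSd, seed = seed)
}

#' Preset decay-only (non-nitrifying) scenario
#'
#' Treatment-plant water with a healthy residual (4.3 mg/L) whose
#' monochloramine decays without any NOx production, sampled weekly over
#' eight weeks.
#'
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @return a \code{DecayScenario}
#' @export
decayOnlyScenario <- function(noiseSd = 0, seed = 1) {
  decayScenario(
    initial = mixtureState(cNH2Cl = 4.3, cNH3N = 0.25, cDOC = 2.4),
    kDecay = 0.03, nitrificationOnset = 0, nitrificationRate = 0,
    docDrift = 0, horizonDays = 56, sampleTimes = seq(0, 56, by = 7),
    noiseSd = noiseSd, seed = seed)
}

#' Six-sample scenario preset
#'
#' Unprocessed, filtered and microbially enhanced variants of two source
#' waters (initial monochloramine 4.3 and 1.3 mg/L), emulating a bench
#' nitrification study: filtering suppresses conversion, enhancement
#' accelerates it, and only the low-residual enhanced sample nitrifies
#' strongly.
#'
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @return named list of six \code{DecayScenario}s
#' @export
sixSampleScenarios <- function(noiseSd = 0.001, seed = 1) {
  mk <- function(c0, nh3, rate, onset, k, i)
    decayScenario(initial = mixtureState(cNH2Cl = c0, cNH3N = nh3, cDOC = 2.4),
                  kDecay = k, nitrificationOnset = onset,
                  nitrificationRate = rate, horizonDays = 56,
                  sampleTimes = seq(0, 56, by = 7), noiseSd = noiseSd,
                  seed = seed + 100 * i)
  list(
    sample1 = mk(4.3, 0.25, 0.010, 14, 0.030, 1),  # WTP unprocessed
    sample2 = mk(4.3, 0.25, 0.000, 0, 0.025, 2),   # WTP filtered
    sample3 = mk(4.3, 1.05, 0.015, 14, 0.040, 3),  # WTP enhanced
    sample4 = mk(1.3, 0.40, 0.020, 10, 0.060, 4),  # system unprocessed
    sample5 = mk(1.3, 0.40, 0.000, 0, 0.050, 5),   # system filtered
    sample6 = mk(1.3, 1.20, 0.080, 7, 0.120, 6))   # system enhanced, nitrifies
}
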
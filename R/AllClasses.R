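# Condition helpers: errors carry a class so the CLI can map them to exit codes.
.stopConfig <- function(...) {
  stop(structure(class = c("nox_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stopValidation <- function(...) {
  stop(structure(class = c("nox_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stopNumerical <- function(...) {
  stop(structure(class = c("nox_numerical_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.WL_TOL <- 1e-6  # nm tolerance for wavelength comparisons

#' WavelengthGrid: a uniform wavelength axis
#'
#' An evenly spaced wavelength axis in nm. The default analysis grid is
#' 200--300 nm at 0.5 nm resolution (201 points), matching a bench
#' spectrophotometer export; the monochloramine-compensation models are fitted
#' on the 200--244.5 nm sub-grid (90 points).
#'
#' @slot startNm first wavelength (nm)
#' @slot stopNm last wavelength (nm)
#' @slot stepNm grid resolution (nm), default 0.5
#' @export
setClass("WavelengthGrid",
         representation(startNm = "numeric", stopNm = "numeric", stepNm = "numeric"),
         prototype(startNm = 200, stopNm = 300, stepNm = 0.5))

setValidity("WavelengthGrid", function(object) {
  if (length(object@startNm) != 1L || length(object@stopNm) != 1L ||
      length(object@stepNm) != 1L)
    return("startNm, stopNm, stepNm must be scalars")
  if (!is.finite(object@startNm) || !is.finite(object@stopNm) ||
      !is.finite(object@stepNm))
    return("grid bounds must be finite")
  if (object@stepNm <= 0) return("stepNm must be > 0")
  if (object@startNm >= object@stopNm) return("startNm must be < stopNm")
  n <- (object@stopNm - object@startNm) / object@stepNm
  if (abs(n - round(n)) > .WL_TOL)
    return("stopNm - startNm must be an integer multiple of stepNm")
  TRUE
})

#' Construct a WavelengthGrid
#'
#' @param startNm,stopNm,stepNm grid bounds and resolution in nm
#' @return a \code{WavelengthGrid}
#' @examples
#' wavelengthGrid(200, 300, 0.5)
#' @export
wavelengthGrid <- function(startNm, stopNm, stepNm = 0.5) {
  new("WavelengthGrid", startNm = startNm, stopNm = stopNm, stepNm = stepNm)
}

#' Default analysis grid, 200--300 nm at 0.5 nm
#' @return a \code{WavelengthGrid}
#' @export
defaultGrid <- function() wavelengthGrid(200, 300, 0.5)

#' Compensation model grid, 200--244.5 nm at 0.5 nm (90 points)
#' @return a \code{WavelengthGrid}
#' @export
compensationGrid <- function() wavelengthGrid(200, 244.5, 0.5)

#' @rdname wavelengths
setMethod("wavelengths", "WavelengthGrid", function(x) {
  n <- round((x@stopNm - x@startNm) / x@stepNm)
  x@startNm + x@stepNm * (0:n)
})

setMethod("length", "WavelengthGrid", function(x) {
  round((x@stopNm - x@startNm) / x@stepNm) + 1L
})

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d points)\n",
              object@startNm, object@stopNm, object@stepNm, length(object)))
})

.sameGrid <- function(a, b) {
  abs(a@startNm - b@startNm) < .WL_TOL &&
    abs(a@stopNm - b@stopNm) < .WL_TOL &&
    abs(a@stepNm - b@stepNm) < .WL_TOL
}

#' Spectrum: one absorbance fingerprint
#'
#' An absorbance spectrum on a \code{WavelengthGrid}, with the optical
#' pathlength and acquisition metadata. Negative absorbances are allowed
#' (instrument noise on a blank-corrected measurement can produce them).
#'
#' @slot grid the \code{WavelengthGrid}
#' @slot absorbance AU values, one per grid point, all finite
#' @slot pathlengthCm optical path in cm (default 10, a 10 cm quartz cell)
#' @slot timestamp acquisition time, ISO-8601 text ("" when unknown)
#' @slot label free-text label
#' @export
setClass("Spectrum",
         representation(grid = "WavelengthGrid", absorbance = "numeric",
                        pathlengthCm = "numeric", timestamp = "character",
                        label = "character"),
         prototype(pathlengthCm = 10, timestamp = "", label = ""))

setValidity("Spectrum", function(object) {
  if (length(object@absorbance) != length(object@grid))
    return("absorbance length must equal grid length")
  if (!all(is.finite(object@absorbance)))
    return("absorbance values must all be finite")
  if (length(object@pathlengthCm) != 1L || !is.finite(object@pathlengthCm) ||
      object@pathlengthCm <= 0)
    return("pathlengthCm must be a single positive number")
  if (length(object@timestamp) != 1L || length(object@label) != 1L)
    return("timestamp and label must be single strings")
  TRUE
})

#' Construct a Spectrum
#'
#' @param grid a \code{WavelengthGrid}
#' @param absorbance AU values, one per grid point
#' @param pathlengthCm optical path in cm
#' @param timestamp acquisition time (ISO-8601 text)
#' @param label free-text label
#' @return a \code{Spectrum}
#' @export
spectrum <- function(grid, absorbance, pathlengthCm = 10, timestamp = "",
                     label = "") {
  new("Spectrum", grid = grid, absorbance = as.numeric(absorbance),
      pathlengthCm = pathlengthCm, timestamp = timestamp, label = label)
}

#' @rdname wavelengths
setMethod("wavelengths", "Spectrum", function(x) wavelengths(x@grid))
#' @rdname absorbance
setMethod("absorbance", "Spectrum", function(x) x@absorbance)
#' @rdname pathlength
setMethod("pathlength", "Spectrum", function(x) x@pathlengthCm)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %g-%g nm (%d pts), path %g cm%s%s\n",
              object@grid@startNm, object@grid@stopNm, length(object@grid),
              object@pathlengthCm,
              if (nzchar(object@label)) paste0(", label '", object@label, "'") else "",
              if (nzchar(object@timestamp)) paste0(", t=", object@timestamp) else ""))
  cat(sprintf("  A range: [%.4g, %.4g] AU\n",
              min(object@absorbance), max(object@absorbance)))
})

#' DifferenceSpectrum: pointwise difference of two spectra
#'
#' @slot grid the common \code{WavelengthGrid}
#' @slot delta AU differences (minuend - subtrahend)
#' @slot minuendLabel,subtrahendLabel labels of the operands
#' @export
setClass("DifferenceSpectrum",
         representation(grid = "WavelengthGrid", delta = "numeric",
                        minuendLabel = "character", subtrahendLabel = "character"),
         prototype(minuendLabel = "", subtrahendLabel = ""))

setValidity("DifferenceSpectrum", function(object) {
  if (length(object@delta) != length(object@grid))
    return("delta length must equal grid length")
  if (!all(is.finite(object@delta))) return("delta values must all be finite")
  TRUE
})

#' @rdname wavelengths
setMethod("wavelengths", "DifferenceSpectrum", function(x) wavelengths(x@grid))
#' @rdname deltaValues
setMethod("deltaValues", "DifferenceSpectrum", function(x) x@delta)

setMethod("show", "DifferenceSpectrum", function(object) {
  cat(sprintf("DifferenceSpectrum: '%s' - '%s', %g-%g nm (%d pts)\n",
              object@minuendLabel, object@subtrahendLabel,
              object@grid@startNm, object@grid@stopNm, length(object@grid)))
})

#' NOxSpectrum: isolated combined nitrate+nitrite spectrum
#'
#' The sample spectrum at time t minus the estimated decay-only spectrum
#' (baseline minus predicted monochloramine-decay offsets). Only the
#' 200--245 nm region carries NOx information; values may be slightly
#' negative from noise and are deliberately not clipped (clipping is a
#' display option, see \code{\link{isolateNox}}).
#'
#' @slot grid the \code{WavelengthGrid}
#' @slot absorbance AU relative to baseline
#' @slot baselineTimestamp,sampleTimestamp acquisition times
#' @export
setClass("NOxSpectrum",
         representation(grid = "WavelengthGrid", absorbance = "numeric",
                        baselineTimestamp = "character",
                        sampleTimestamp = "character"),
         prototype(baselineTimestamp = "", sampleTimestamp = ""))

setValidity("NOxSpectrum", function(object) {
  if (length(object@absorbance) != length(object@grid))
    return("absorbance length must equal grid length")
  if (!all(is.finite(object@absorbance))) return("values must be finite")
  TRUE
})

#' @rdname wavelengths
setMethod("wavelengths", "NOxSpectrum", function(x) wavelengths(x@grid))
#' @rdname absorbance
setMethod("absorbance", "NOxSpectrum", function(x) x@absorbance)

setMethod("show", "NOxSpectrum", function(object) {
  cat(sprintf("NOxSpectrum: %g-%g nm (%d pts), baseline t=%s, sample t=%s\n",
              object@grid@startNm, object@grid@stopNm, length(object@grid),
              if (nzchar(object@baselineTimestamp)) object@baselineTimestamp else "?",
              if (nzchar(object@sampleTimestamp)) object@sampleTimestamp else "?"))
})

#' ExtinctionCurve: absorptivity of one component
#'
#' Absorptivity per unit concentration per cm path on a wavelength grid.
#' Units: AU per (mg/L) per cm for monochloramine, AU per (mg-N/L) per cm
#' for nitrite/nitrate, AU per (mg-C/L) per cm for NOM.
#'
#' @slot species one of "monochloramine", "nitrite_N", "nitrate_N", "NOM"
#' @slot grid the \code{WavelengthGrid}
#' @slot epsilon absorptivity values, all >= 0
#' @export
setClass("ExtinctionCurve",
         representation(species = "character", grid = "WavelengthGrid",
                        epsilon = "numeric"))

setValidity("ExtinctionCurve", function(object) {
  if (length(object@epsilon) != length(object@grid))
    return("epsilon length must equal grid length")
  if (any(!is.finite(object@epsilon)) || any(object@epsilon < 0))
    return("epsilon must be finite and >= 0")
  if (length(object@species) != 1L) return("species must be a single string")
  TRUE
})

#' @rdname wavelengths
setMethod("wavelengths", "ExtinctionCurve", function(x) wavelengths(x@grid))

setMethod("show", "ExtinctionCurve", function(object) {
  peak <- wavelengths(object)[which.max(object@epsilon)]
  cat(sprintf("ExtinctionCurve '%s': %g-%g nm, max at %g nm (%.4g)\n",
              object@species, object@grid@startNm, object@grid@stopNm,
              peak, max(object@epsilon)))
})

#' MixtureState: component concentrations of one water sample
#'
#' Ammonia is tracked for nitrogen bookkeeping but is spectrally inert at
#' drinking-water concentrations; NOM is quantified as dissolved organic
#' carbon (DOC).
#'
#' @slot cNH2Cl monochloramine, mg/L
#' @slot cNO2N nitrite, mg-N/L
#' @slot cNO3N nitrate, mg-N/L
#' @slot cNH3N free ammonia, mg-N/L (no UV absorbance)
#' @slot cDOC dissolved organic carbon, mg-C/L
#' @export
setClass("MixtureState",
         representation(cNH2Cl = "numeric", cNO2N = "numeric", cNO3N = "numeric",
                        cNH3N = "numeric", cDOC = "numeric"),
         prototype(cNH2Cl = 0, cNO2N = 0, cNO3N = 0, cNH3N = 0, cDOC = 0))

setValidity("MixtureState", function(object) {
  v <- c(object@cNH2Cl, object@cNO2N, object@cNO3N, object@cNH3N, object@cDOC)
  if (length(v) != 5L || any(!is.finite(v))) return("concentrations must be finite scalars")
  if (any(v < 0)) return("concentrations must be >= 0")
  TRUE
})

#' Construct a MixtureState
#'
#' @param cNH2Cl monochloramine mg/L
#' @param cNO2N nitrite mg-N/L
#' @param cNO3N nitrate mg-N/L
#' @param cNH3N free ammonia mg-N/L
#' @param cDOC dissolved organic carbon mg-C/L
#' @return a \code{MixtureState}
#' @export
mixtureState <- function(cNH2Cl = 0, cNO2N = 0, cNO3N = 0, cNH3N = 0, cDOC = 0) {
  new("MixtureState", cNH2Cl = cNH2Cl, cNO2N = cNO2N, cNO3N = cNO3N,
      cNH3N = cNH3N, cDOC = cDOC)
}

setMethod("show", "MixtureState", function(object) {
  cat(sprintf(paste0("MixtureState: NH2Cl %.3g mg/L, NO2-N %.3g, NO3-N %.3g, ",
                     "NH3-N %.3g mg-N/L, DOC %.3g mg-C/L\n"),
              object@cNH2Cl, object@cNO2N, object@cNO3N, object@cNH3N,
              object@cDOC))
})

#' DecayScenario: a chloramine-decay / nitrification time course
#'
#' First-order monochloramine decay releases free ammonia at a fixed
#' stoichiometric yield; after an onset lag, available ammonia-N is converted
#' to NOx-N along a logistic (tanh) curve, split between nitrite and nitrate.
#' DOC may drift linearly over the horizon (uncompensated by the method,
#' which assumes NOM stable over short windows).
#'
#' @slot initial starting \code{MixtureState}
#' @slot kDecay first-order monochloramine decay rate, 1/day
#' @slot nitrificationOnset onset lag, days
#' @slot nitrificationRate logistic conversion rate, 1/day
#' @slot nitriteFraction fraction of converted N appearing as nitrite
#' @slot ammoniaYield mg-N released per mg NH2Cl decayed (default 0.25)
#' @slot docDrift linear DOC decrease over the horizon, mg-C/L (>= 0)
#' @slot horizonDays scenario length, days
#' @slot sampleTimes sampling times, days (first is the baseline)
#' @slot noiseSd instrument noise, AU
#' @slot seed RNG seed for the noise
#' @export
setClass("DecayScenario",
         representation(initial = "MixtureState", kDecay = "numeric",
                        nitrificationOnset = "numeric", nitrificationRate = "numeric",
                        nitriteFraction = "numeric", ammoniaYield = "numeric",
                        docDrift = "numeric", horizonDays = "numeric",
                        sampleTimes = "numeric", noiseSd = "numeric",
                        seed = "numeric"))

setValidity("DecayScenario", function(object) {
  if (object@kDecay < 0) return("kDecay must be >= 0")
  if (object@horizonDays <= 0) return("horizonDays must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nitrificationRate < 0) return("nitrificationRate must be >= 0")
  if (object@nitriteFraction < 0 || object@nitriteFraction > 1)
    return("nitriteFraction must lie in [0, 1]")
  if (object@ammoniaYield < 0) return("ammoniaYield must be >= 0")
  if (object@docDrift < 0) return("docDrift (a decrease) must be >= 0")
  if (length(object@sampleTimes) && any(object@sampleTimes < 0))
    return("sampleTimes must be >= 0")
  if (is.unsorted(object@sampleTimes, strictly = TRUE))
    return("sampleTimes must be strictly increasing")
  TRUE
})

#' Construct a DecayScenario
#'
#' @param initial starting \code{MixtureState}
#' @param kDecay first-order monochloramine decay rate (1/day)
#' @param nitrificationOnset onset lag (days)
#' @param nitrificationRate logistic ammonia-to-NOx conversion rate (1/day)
#' @param nitriteFraction nitrite share of converted N
#' @param ammoniaYield mg-N released per mg NH2Cl decayed
#' @param docDrift linear DOC decrease over the horizon (mg-C/L)
#' @param horizonDays scenario length (days)
#' @param sampleTimes sampling days, strictly increasing, first = baseline
#' @param noiseSd instrument noise (AU)
#' @param seed RNG seed
#' @return a \code{DecayScenario}
#' @export
decayScenario <- function(initial, kDecay, nitrificationOnset = 0,
                          nitrificationRate = 0, nitriteFraction = 0.5,
                          ammoniaYield = 0.25, docDrift = 0,
                          horizonDays = max(sampleTimes, 1),
                          sampleTimes, noiseSd = 0, seed = 1) {
  new("DecayScenario", initial = initial, kDecay = kDecay,
      nitrificationOnset = nitrificationOnset,
      nitrificationRate = nitrificationRate, nitriteFraction = nitriteFraction,
      ammoniaYield = ammoniaYield, docDrift = docDrift,
      horizonDays = horizonDays, sampleTimes = as.numeric(sampleTimes),
      noiseSd = noiseSd, seed = seed)
}

#' DeltaDataset: pairwise spectra differences from a calibration series
#'
#' One record per unordered pair of calibration spectra, oriented
#' higher-concentration minus lower so the anchor offsets are nonnegative.
#'
#' @slot anchorNm anchor wavelength (245 nm)
#' @slot anchor anchor offsets, one per record (AU)
#' @slot deltas record-by-wavelength matrix of offsets on the modelled grid
#' @slot modelledWavelengths modelled wavelengths, 200--244.5 nm
#' @slot concRange concentration range of the calibration series (mg/L)
#' @export
setClass("DeltaDataset",
         representation(anchorNm = "numeric", anchor = "numeric",
                        deltas = "matrix", modelledWavelengths = "numeric",
                        concRange = "numeric"))

setValidity("DeltaDataset", function(object) {
  if (nrow(object@deltas) != length(object@anchor))
    return("one anchor value per record required")
  if (ncol(object@deltas) != length(object@modelledWavelengths))
    return("delta columns must match modelled wavelengths")
  if (any(object@anchor < -.WL_TOL))
    return("anchor offsets must be >= 0 (higher-minus-lower orientation)")
  TRUE
})

setMethod("show", "DeltaDataset", function(object) {
  cat(sprintf("DeltaDataset: %d pair records, anchor %g nm, %d modelled wavelengths\n",
              length(object@anchor), object@anchorNm,
              length(object@modelledWavelengths)))
})

#' CompensationModel: per-wavelength linear decay-compensation model
#'
#' Ordinary least-squares lines relating the anchor offset (245 nm) to the
#' offset at each modelled wavelength, with per-wavelength fit diagnostics.
#'
#' @slot anchorNm anchor wavelength
#' @slot wavelengthsNm modelled wavelengths (200--244.5 nm)
#' @slot slope,intercept per-wavelength line coefficients
#' @slot r2 per-wavelength squared Pearson correlation of the fit
#' @slot rmse per-wavelength root-mean-square residual (AU)
#' @slot nRecords number of pair records used
#' @slot concRange calibration concentration range (mg/L)
#' @export
setClass("CompensationModel",
         representation(anchorNm = "numeric", wavelengthsNm = "numeric",
                        slope = "numeric", intercept = "numeric",
                        r2 = "numeric", rmse = "numeric",
                        nRecords = "integer", concRange = "numeric"))

setValidity("CompensationModel", function(object) {
  n <- length(object@wavelengthsNm)
  if (length(object@slope) != n || length(object@intercept) != n ||
      length(object@r2) != n || length(object@rmse) != n)
    return("one slope/intercept/r2/rmse entry per modelled wavelength required")
  if (any(object@r2 < -.WL_TOL | object@r2 > 1 + .WL_TOL, na.rm = TRUE))
    return("r2 must lie in [0, 1]")
  if (any(object@rmse < 0, na.rm = TRUE)) return("rmse must be >= 0")
  TRUE
})

setMethod("show", "CompensationModel", function(object) {
  cat(sprintf("CompensationModel: anchor %g nm, %d wavelengths, %d pair records\n",
              object@anchorNm, length(object@wavelengthsNm), object@nRecords))
  cat(sprintf("  R2 range [%.4f, %.4f]; RMSE range [%.2e, %.2e] AU\n",
              min(object@r2), max(object@r2), min(object@rmse), max(object@rmse)))
})

#' FeatureScaler: per-feature min-max map onto [-1, +1]
#'
#' Affine map sending the training minimum to -1 and maximum to +1 per
#' feature; constant features map to 0. Values outside the training range
#' map outside [-1, +1] (no clipping).
#'
#' @slot mins,maxs per-feature training extrema
#' @export
setClass("FeatureScaler", representation(mins = "numeric", maxs = "numeric"))

setValidity("FeatureScaler", function(object) {
  if (length(object@mins) != length(object@maxs))
    return("mins and maxs must have equal length")
  if (any(object@maxs < object@mins)) return("max must be >= min per feature")
  TRUE
})

#' NOxRegressor: kernel regression from NOx spectra to mg-N/L
#'
#' A support-vector regression (epsilon-insensitive, default RBF kernel) on
#' min-max scaled absorbance features over a wavelength window. The kernel
#' expansion (support vectors, coefficients, offset) is stored explicitly so
#' the model can be persisted as plain text and evaluated without the
#' original fit object.
#'
#' @slot kernel one of "linear", "polynomial", "radial", "sigmoid"
#' @slot C penalty parameter (> 0)
#' @slot gamma kernel width (> 0)
#' @slot epsilon insensitivity margin (scaled label units, >= 0)
#' @slot degree,coef0 polynomial/sigmoid kernel constants
#' @slot featureScaler,labelScaler min-max scalers fitted on training data
#' @slot windowNm wavelength window (min, max) of the features
#' @slot wavelengthsNm feature wavelengths
#' @slot sv support-vector matrix (scaled feature space)
#' @slot svCoefs kernel-expansion coefficients
#' @slot rho decision-function offset (prediction = K %*% coefs - rho)
#' @slot nSamples training-set size
#' @slot maxLabel largest training label, mg-N/L (extrapolation threshold)
#' @export
setClass("NOxRegressor",
         representation(kernel = "character", cost = "numeric", gamma = "numeric",
                        epsilon = "numeric", degree = "numeric", coef0 = "numeric",
                        featureScaler = "FeatureScaler", labelScaler = "FeatureScaler",
                        windowNm = "numeric", wavelengthsNm = "numeric",
                        sv = "matrix", svCoefs = "numeric", rho = "numeric",
                        nSamples = "integer", maxLabel = "numeric"))

setValidity("NOxRegressor", function(object) {
  if (!object@kernel %in% c("linear", "polynomial", "radial", "sigmoid"))
    return("unknown kernel")
  if (object@cost <= 0) return("cost (C) must be > 0")
  if (object@gamma <= 0) return("gamma must be > 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (nrow(object@sv) != length(object@svCoefs))
    return("one coefficient per support vector required")
  TRUE
})

setMethod("show", "NOxRegressor", function(object) {
  cat(sprintf(paste0("NOxRegressor: %s kernel, C=%g, gamma=%g, epsilon=%g\n",
                     "  %d support vectors, window %g-%g nm (%d features), ",
                     "trained on %d samples, max label %g mg-N/L\n"),
              object@kernel, object@cost, object@gamma, object@epsilon,
              nrow(object@sv), object@windowNm[1], object@windowNm[2],
              length(object@wavelengthsNm), object@nSamples, object@maxLabel))
})

#' CVReport: cross-validation and grid-search record
#'
#' @slot folds number of folds (10 by default)
#' @slot foldAssign fold index per training sample
#' @slot perFold per-fold validation R2 and RMSE for the selected parameters
#' @slot cvR2,cvRmse pooled validation R2 / RMSE (mg-N/L)
#' @slot trainR2,trainRmse metrics of the final refit on all data
#' @slot trace grid-search trace (C, gamma, pooled validation RMSE)
#' @slot seed RNG seed used for the fold shuffle
#' @export
setClass("CVReport",
         representation(folds = "integer", foldAssign = "integer",
                        perFold = "data.frame", cvR2 = "numeric",
                        cvRmse = "numeric", trainR2 = "numeric",
                        trainRmse = "numeric", trace = "data.frame",
                        seed = "numeric"))

setMethod("show", "CVReport", function(object) {
  cat(sprintf(paste0("CVReport: %d-fold CV, pooled R2 %.4f, RMSE %.4g mg-N/L; ",
                     "training R2 %.4f, RMSE %.4g\n"),
              object@folds, object@cvR2, object@cvRmse, object@trainR2,
              object@trainRmse))
  cat(sprintf("  grid search: %d parameter tuples, seed %g\n",
              nrow(object@trace), object@seed))
})

#' LocalCalibration: site-specific linear correction
#'
#' Least-squares line relating laboratory NOx-N measurements to raw model
#' predictions: lab = slope * predicted + intercept.
#'
#' @slot slope,intercept line coefficients
#' @slot r2 squared Pearson correlation of the fit
#' @slot n number of calibration points
#' @export
setClass("LocalCalibration",
         representation(slope = "numeric", intercept = "numeric",
                        r2 = "numeric", n = "integer"))

setMethod("show", "LocalCalibration", function(object) {
  cat(sprintf("LocalCalibration: lab = %.4g * predicted + %.4g (R2 %.3f, n=%d)\n",
              object@slope, object@intercept, object@r2, object@n))
})
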
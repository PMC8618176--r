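# Monitoring pipeline: baseline + time-ordered spectra -> per-timestamp
# anchor offset, isolated NOx spectrum, relative NOx-N estimate, and
# nitrification alert flags.

#' Run the nitrification-monitoring pipeline over a spectra series
#'
#' For each spectrum after the baseline: align grids, take the anchor offset
#' (baseline minus sample at 245 nm), predict the per-wavelength decay
#' offsets, estimate the decay-only spectrum, isolate the NOx spectrum,
#' predict the relative NOx-N concentration (optionally locally calibrated),
#' and compare against the alert threshold. The first spectrum of the series
#' is the baseline unless one is supplied.
#'
#' @param spectra list of \code{Spectrum} in time order (first = baseline
#'   when \code{baseline} is NULL)
#' @param compModel a \code{CompensationModel}
#' @param regressor a \code{NOxRegressor}
#' @param baseline optional explicit baseline \code{Spectrum} (re-baselining)
#' @param localCal optional \code{LocalCalibration}
#' @param threshold nitrification alert threshold, mg-N/L (default 0.05: a
#'   relative NOx-N rise at or above it warrants investigation)
#' @param tail decay-estimate rule past the anchor (see
#'   \code{\link{estimateDecaySpectrum}})
#' @return data.frame with one row per non-baseline timestamp: timestamp,
#'   delta245_AU, nox_rel_mgN_L, nox_cal_mgN_L (NA without local
#'   calibration), extrapolated, alert
#' @export
monitorSeries <- function(spectra, compModel, regressor, baseline = NULL,
                          localCal = NULL, threshold = 0.05,
                          tail = c("mirror", "zero")) {
  tail <- match.arg(tail)
  if (is.null(baseline)) {
    if (length(spectra) < 2L)
      .stopConfig("need a baseline plus at least one subsequent spectrum")
    baseline <- spectra[[1]]
    spectra <- spectra[-1]
  } else if (!length(spectra)) {
    .stopConfig("need at least one spectrum after the baseline")
  }
  rows <- lapply(spectra, function(s) {
    s <- alignToGrid(s, baseline@grid)
    d <- subtractSpectra(baseline, s)          # positive where absorbance fell
    dAnchor <- deltaAt(d, compModel@anchorNm)
    deltas <- predictDeltas(compModel, dAnchor)
    decayEst <- estimateDecaySpectrum(baseline, deltas, dAnchor,
                                      anchorNm = compModel@anchorNm,
                                      modelWl = compModel@wavelengthsNm,
                                      tail = tail)
    nox <- isolateNox(s, decayEst)
    pred <- predictNox(regressor, nox)
    cal <- if (!is.null(localCal)) applyCalibration(localCal, pred)
           else NA_real_
    eff <- if (!is.null(localCal)) cal else pred
    data.frame(timestamp = if (nzchar(s@timestamp)) s@timestamp else s@label,
               delta245_AU = dAnchor,
               nox_rel_mgN_L = as.numeric(pred),
               nox_cal_mgN_L = as.numeric(cal),
               extrapolated = as.logical(attr(pred, "extrapolated")),
               alert = as.numeric(eff) >= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
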
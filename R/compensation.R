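# Monochloramine-decay compensation: per-wavelength linear models anchored at
# the 245 nm offset, fitted from a pure-monochloramine concentration series
# in ultrapure water, then used to estimate the decay-only spectrum of a
# sample and isolate the combined nitrate+nitrite difference spectrum.

#' Pairwise spectra differences of a calibration series
#'
#' Builds the dataset behind the compensation fit: for every unordered pair
#' of calibration spectra (all possible concentration combinations), the
#' difference oriented higher-concentration minus lower is taken at the
#' anchor wavelength (245 nm) and at every modelled wavelength
#' (200--244.5 nm, 0.5 nm steps).
#'
#' @param calibration list of \code{Spectrum} ordered by increasing
#'   concentration, on a common grid covering 200--245 nm; at least 3
#' @param concentrations optional concentrations (mg/L) for provenance
#' @param anchorNm anchor wavelength, default 245
#' @param modelledGrid the modelled wavelengths, default 200--244.5 nm
#' @param pairs \code{"all"} for all C(n,2) pairs (default) or
#'   \code{"baseline"} for pairs against the first (lowest) spectrum only
#' @return a \code{DeltaDataset} with C(n,2) (or n-1) records
#' @export
computePairwiseDeltas <- function(calibration, concentrations = NULL,
                                  anchorNm = 245,
                                  modelledGrid = compensationGrid(),
                                  pairs = c("all", "baseline")) {
  pairs <- match.arg(pairs)
  n <- length(calibration)
  if (n < 3L)
    .stopValidation("insufficient calibration: need >= 3 spectra, got ", n)
  g <- calibration[[1]]@grid
  for (s in calibration)
    if (!.sameGrid(s@grid, g))
      .stopValidation("calibration spectra are not on a common grid")
  wl <- wavelengths(g)
  mwl <- wavelengths(modelledGrid)
  if (mwl[1] < wl[1] - .WL_TOL || anchorNm > wl[length(wl)] + .WL_TOL)
    .stopValidation("calibration grid must cover the modelled range and ",
                    anchorNm, " nm")
  idxPairs <- if (pairs == "all") {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # (lo, hi) with lo < hi
  } else {
    cbind(rep(1L, n - 1L), 2:n)
  }
  # interpolate each spectrum once onto modelled wavelengths + anchor
  qwl <- c(mwl, anchorNm)
  vals <- vapply(calibration,
                 function(s) stats::approx(wl, s@absorbance, xout = qwl,
                                           rule = 1)$y,
                 numeric(length(qwl)))
  hi <- idxPairs[, 2]; lo <- idxPairs[, 1]
  dmat <- t(vals[, hi, drop = FALSE] - vals[, lo, drop = FALSE])
  anchor <- dmat[, length(qwl)]
  deltas <- dmat[, -length(qwl), drop = FALSE]
  colnames(deltas) <- format(mwl)
  cr <- if (!is.null(concentrations)) range(concentrations)
        else c(NA_real_, NA_real_)
  new("DeltaDataset", anchorNm = anchorNm, anchor = pmax(anchor, 0),
      deltas = deltas, modelledWavelengths = mwl, concRange = cr)
}

#' Fit the per-wavelength linear compensation model
#'
#' Ordinary least squares of the offset at each modelled wavelength against
#' the anchor offset, intercept included. Per-wavelength diagnostics are the
#' squared Pearson correlation (\code{\link{rSquared}}) and the
#' root-mean-square residual (\code{\link{rmse}}). On clean Beer-Lambert
#' data the slopes equal the absorptivity ratio eps(lambda)/eps(245) and the
#' intercepts vanish.
#'
#' @param data a \code{DeltaDataset} with >= 3 records and non-degenerate
#'   anchor spread
#' @return a \code{CompensationModel}
#' @export
fitCompensation <- function(data) {
  x <- data@anchor
  if (length(x) < 3L)
    .stopValidation("insufficient calibration: need >= 3 pair records")
  if (stats::sd(x) < 1e-12)
    .stopNumerical("rank deficiency: all anchor offsets are equal")
  Y <- data@deltas
  mx <- mean(x)
  vx <- sum((x - mx)^2)
  my <- colMeans(Y)
  slope <- as.numeric(crossprod(x - mx, sweep(Y, 2, my)) / vx)
  intercept <- unname(my - slope * mx)
  fitted <- outer(x, slope) + rep(intercept, each = length(x))
  resid <- Y - fitted
  rmseW <- unname(sqrt(colMeans(resid^2)))
  r2 <- vapply(seq_len(ncol(Y)), function(j) {
    sy <- stats::sd(Y[, j])
    if (sy < 1e-15) return(NA_real_)
    stats::cor(x, Y[, j])^2
  }, numeric(1))
  new("CompensationModel", anchorNm = data@anchorNm,
      wavelengthsNm = data@modelledWavelengths, slope = slope,
      intercept = intercept, r2 = pmin(pmax(r2, 0), 1), rmse = rmseW,
      nRecords = length(x), concRange = data@concRange)
}

#' Predict per-wavelength decay offsets from a sample's anchor offset
#'
#' \eqn{\hat\Delta_i = slope_i \Delta_{245} + intercept_i} for every
#' modelled wavelength. A negative anchor (absorbance rose at 245 nm, which
#' monochloramine decay cannot produce) triggers a warning and returns zero
#' offsets: no compensation is applied.
#'
#' @param model a fitted \code{CompensationModel}
#' @param deltaAnchorSample the sample's baseline-minus-sample offset at the
#'   anchor wavelength (AU)
#' @return named vector of predicted offsets on the modelled grid
#' @export
predictDeltas <- function(model, deltaAnchorSample) {
  if (!length(model@slope)) .stopNumerical("compensation model is not fitted")
  if (deltaAnchorSample < 0) {
    warning("negative anchor offset (absorbance rose at ", model@anchorNm,
            " nm): interference suspected, no compensation applied",
            call. = FALSE)
    d <- rep(0, length(model@wavelengthsNm))
  } else {
    d <- model@slope * deltaAnchorSample + model@intercept
  }
  names(d) <- format(model@wavelengthsNm)
  d
}

# Predicted decay offset over a full baseline grid. Modelled range: the
# fitted deltas; the anchor wavelength: the observed anchor offset; beyond
# the anchor: "mirror" reflects the modelled offsets about the anchor (the
# monochloramine band is symmetric) and falls to zero where the mirror
# leaves the modelled range, "zero" applies no compensation past the anchor.
.deltaOnGrid <- function(wl, modelWl, deltas, anchorNm, anchorDelta,
                         tail = c("mirror", "zero")) {
  tail <- match.arg(tail)
  out <- numeric(length(wl))
  below <- wl <= modelWl[length(modelWl)] + .WL_TOL
  out[below] <- stats::approx(modelWl, deltas, xout = wl[below], rule = 2)$y
  atAnchor <- abs(wl - anchorNm) < .WL_TOL
  out[atAnchor] <- anchorDelta
  above <- wl > anchorNm + .WL_TOL
  if (any(above)) {
    if (tail == "mirror") {
      mirrored <- 2 * anchorNm - wl[above]
      ok <- mirrored >= modelWl[1] - .WL_TOL
      vals <- numeric(sum(above))
      vals[ok] <- stats::approx(modelWl, deltas, xout = mirrored[ok],
                                rule = 2)$y
      out[above] <- vals
    }  # "zero": leave at 0
  }
  # between the last modelled wavelength and the anchor (exclusive), bridge
  # linearly so the estimate is continuous
  gap <- wl > modelWl[length(modelWl)] + .WL_TOL & wl < anchorNm - .WL_TOL
  if (any(gap)) {
    out[gap] <- stats::approx(c(modelWl[length(modelWl)], anchorNm),
                              c(deltas[length(deltas)], anchorDelta),
                              xout = wl[gap])$y
  }
  out
}

#' Estimate the decay-only spectrum of a sample
#'
#' Subtracts the predicted per-wavelength decay offsets from the baseline to
#' approximate the spectrum at time t attributable to NOM plus remaining
#' monochloramine only (no NOx absorbance). On the modelled grid the
#' estimate is baseline minus the predicted offsets; at the anchor
#' wavelength the observed anchor offset is used; beyond the anchor a
#' mirrored-band rule (default) or zero compensation applies. NOx
#' quantification only uses 200--245 nm, so the tail rule cannot affect
#' concentrations.
#'
#' @param baseline the series baseline \code{Spectrum} (covers the modelled
#'   grid and the anchor wavelength)
#' @param deltas predicted offsets from \code{\link{predictDeltas}}
#' @param anchorDelta observed baseline-minus-sample offset at the anchor
#' @param anchorNm anchor wavelength
#' @param modelWl modelled wavelengths matching \code{deltas}
#' @param tail tail rule past the anchor: \code{"mirror"} or \code{"zero"}
#' @return a \code{Spectrum} on the baseline grid
#' @export
estimateDecaySpectrum <- function(baseline, deltas,
                                  anchorDelta, anchorNm = 245,
                                  modelWl = wavelengths(compensationGrid()),
                                  tail = c("mirror", "zero")) {
  wl <- wavelengths(baseline)
  if (wl[1] > modelWl[1] + .WL_TOL || wl[length(wl)] < anchorNm - .WL_TOL)
    .stopValidation("baseline grid must cover the modelled range and the anchor")
  if (length(deltas) != length(modelWl))
    .stopValidation("deltas length must match the modelled wavelengths")
  dAll <- .deltaOnGrid(wl, modelWl, as.numeric(deltas), anchorNm, anchorDelta,
                       tail = match.arg(tail))
  spectrum(baseline@grid, baseline@absorbance - dAll,
           pathlengthCm = baseline@pathlengthCm,
           timestamp = baseline@timestamp,
           label = "decay-only estimate")
}

#' Isolate the NOx difference spectrum
#'
#' Subtracts the estimated decay-only spectrum from the recorded sample
#' spectrum; what remains is the absorbance attributable to nitrate +
#' nitrite produced since the baseline. Values may be slightly negative
#' from noise; prediction consumes them unclipped, \code{clip = TRUE} is a
#' display option only.
#'
#' @param sample the recorded \code{Spectrum} at time t
#' @param estimatedDecay the decay-only estimate from
#'   \code{\link{estimateDecaySpectrum}}
#' @param clip clip negative values at zero (display only)
#' @return a \code{NOxSpectrum}
#' @export
isolateNox <- function(sample, estimatedDecay, clip = FALSE) {
  if (!.sameGrid(sample@grid, estimatedDecay@grid))
    .stopValidation("grid mismatch between sample and decay estimate")
  a <- sample@absorbance - estimatedDecay@absorbance
  if (clip) a <- pmax(a, 0)
  new("NOxSpectrum", grid = sample@grid, absorbance = a,
      baselineTimestamp = estimatedDecay@timestamp,
      sampleTimestamp = sample@timestamp)
}

.COMP_SCHEMA <- "nox-compensation-1"

#' Persist a compensation model as JSON
#'
#' @param model a \code{CompensationModel}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCompensationModel <- function(model, path) {
  obj <- list(schema = .COMP_SCHEMA, anchor_nm = model@anchorNm,
              wavelengths_nm = model@wavelengthsNm, slope = model@slope,
              intercept = model@intercept, r2 = model@r2, rmse = model@rmse,
              n_records = model@nRecords, conc_range = model@concRange)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a compensation model from JSON
#'
#' @param path file written by \code{\link{writeCompensationModel}}
#' @return a \code{CompensationModel}
#' @export
readCompensationModel <- function(path) {
  if (!file.exists(path)) .stopConfig("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, .COMP_SCHEMA))
    .stopConfig("unrecognized compensation model schema: ", obj$schema)
  new("CompensationModel", anchorNm = obj$anchor_nm,
      wavelengthsNm = obj$wavelengths_nm, slope = obj$slope,
      intercept = obj$intercept, r2 = obj$r2, rmse = obj$rmse,
      nRecords = as.integer(obj$n_records),
      concRange = as.numeric(obj$conc_range))
}
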
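# Spectrum arithmetic and resampling.

#' @rdname alignToGrid
setMethod("alignToGrid", signature("Spectrum", "WavelengthGrid"), function(x, grid) {
  if (.sameGrid(x@grid, grid)) return(x)
  wlOld <- wavelengths(x)
  wlNew <- wavelengths(grid)
  if (wlNew[1] < wlOld[1] - .WL_TOL ||
      wlNew[length(wlNew)] > wlOld[length(wlOld)] + .WL_TOL)
    .stopValidation("requested grid lies outside the spectrum's wavelength span")
  ab <- stats::approx(wlOld, x@absorbance, xout = wlNew, rule = 1)$y
  spectrum(grid, ab, pathlengthCm = x@pathlengthCm, timestamp = x@timestamp,
           label = x@label)
})

#' @rdname alignToGrid
setMethod("alignToGrid", signature("ExtinctionCurve", "WavelengthGrid"),
          function(x, grid) {
  if (.sameGrid(x@grid, grid)) return(x)
  wlOld <- wavelengths(x)
  wlNew <- wavelengths(grid)
  if (wlNew[1] < wlOld[1] - .WL_TOL ||
      wlNew[length(wlNew)] > wlOld[length(wlOld)] + .WL_TOL)
    .stopValidation("requested grid lies outside the curve's wavelength span")
  eps <- stats::approx(wlOld, x@epsilon, xout = wlNew, rule = 1)$y
  new("ExtinctionCurve", species = x@species, grid = grid, epsilon = eps)
})

#' Subtract two spectra
#'
#' Pointwise difference \code{a - b}. Both spectra must share one grid and
#' pathlength; align first with \code{\link{alignToGrid}} when they do not.
#' The operator form \code{a - b} is equivalent.
#'
#' @param a,b \code{Spectrum} objects on a common grid
#' @return a \code{DifferenceSpectrum} (antisymmetric under operand swap)
#' @export
subtractSpectra <- function(a, b) {
  if (!.sameGrid(a@grid, b@grid))
    .stopValidation("grid mismatch: align the spectra to a common grid first")
  if (abs(a@pathlengthCm - b@pathlengthCm) > .WL_TOL)
    .stopValidation("pathlength mismatch: operations do not rescale pathlengths")
  new("DifferenceSpectrum", grid = a@grid, delta = a@absorbance - b@absorbance,
      minuendLabel = a@label, subtrahendLabel = b@label)
}

#' @rdname subtractSpectra
#' @aliases -,Spectrum,Spectrum-method
setMethod("-", signature("Spectrum", "Spectrum"),
          function(e1, e2) subtractSpectra(e1, e2))

#' Offset of a difference spectrum at one wavelength
#'
#' Returns the difference value at a wavelength, interpolating linearly when
#' the wavelength falls between grid points. The canonical anchor for
#' monochloramine-decay compensation is 245 nm.
#'
#' @param d a \code{DifferenceSpectrum}
#' @param wavelength query wavelength (nm), within the grid span
#' @return the offset in AU
#' @export
deltaAt <- function(d, wavelength) {
  wl <- wavelengths(d)
  if (wavelength < wl[1] - .WL_TOL || wavelength > wl[length(wl)] + .WL_TOL)
    .stopValidation("wavelength ", wavelength, " nm outside the grid span ",
                    wl[1], "-", wl[length(wl)], " nm")
  hit <- which(abs(wl - wavelength) < .WL_TOL)
  if (length(hit)) return(d@delta[hit[1]])
  stats::approx(wl, d@delta, xout = wavelength, rule = 1)$y
}

#' Apparent peak wavelength of a spectrum
#'
#' The wavelength of maximum absorbance within a window. When several points
#' tie at the maximum (e.g. a detector-saturation plateau) the midpoint of
#' the maximal plateau is reported, which is how a flat-topped band reads by
#' eye on a plot.
#'
#' @param s a \code{Spectrum}, \code{NOxSpectrum} or \code{ExtinctionCurve}
#' @param windowNm optional c(min, max) wavelength window in nm
#' @param tol tie tolerance in AU
#' @return apparent peak wavelength in nm
#' @export
peakWavelength <- function(s, windowNm = NULL, tol = 1e-9) {
  wl <- wavelengths(s)
  y <- if (is(s, "ExtinctionCurve")) s@epsilon else absorbance(s)
  if (!is.null(windowNm)) {
    keep <- wl >= windowNm[1] - .WL_TOL & wl <= windowNm[2] + .WL_TOL
    if (!any(keep)) .stopValidation("window contains no grid points")
    wl <- wl[keep]; y <- y[keep]
  }
  top <- which(y >= max(y) - tol)
  mean(range(wl[top]))
}
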
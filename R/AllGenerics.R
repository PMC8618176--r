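#' @import methods
NULL

#' Wavelength vector of an object
#'
#' Returns the wavelength axis (nm) of a grid, spectrum, extinction curve or
#' difference spectrum.
#'
#' @param x an object carrying a wavelength grid
#' @return numeric vector of wavelengths in nm, strictly increasing
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Absorbance values of a spectrum-like object
#'
#' @param x a \code{Spectrum} or \code{NOxSpectrum}
#' @return numeric vector of absorbance values (AU), one per grid point
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Optical pathlength of a spectrum
#'
#' @param x a \code{Spectrum}
#' @return pathlength in cm
#' @export
setGeneric("pathlength", function(x) standardGeneric("pathlength"))

#' Difference values of a DifferenceSpectrum
#'
#' @param x a \code{DifferenceSpectrum}
#' @return numeric vector of absorbance differences (AU)
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))

#' Resample a spectrum-like object onto a wavelength grid
#'
#' Linear interpolation onto the target grid; exact pass-through when the
#' grids coincide. The requested grid must lie within the object's span.
#'
#' @param x a \code{Spectrum} (or \code{ExtinctionCurve})
#' @param grid target \code{WavelengthGrid}
#' @return object of the same class on the new grid
#' @export
setGeneric("alignToGrid", function(x, grid) standardGeneric("alignToGrid"))
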
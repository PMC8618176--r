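# Spectrum file I/O.
#
# Long dialect: header "wavelength_nm,absorbance", optional leading comment
# lines "# key: value" carrying timestamp / label / pathlength_cm.
# Wide dialect: "wavelength_nm,<label_1>,<label_2>,..." with one column per
# spectrum; labels carry ISO-8601 timestamps when used for monitoring.

.gridFromWavelengths <- function(wl) {
  if (length(wl) < 2L) .stopValidation("need at least 2 wavelength points")
  if (is.unsorted(wl, strictly = TRUE))
    .stopValidation("wavelengths must be strictly increasing (duplicated or ",
                    "unordered wavelength rows found)")
  steps <- diff(wl)
  if (max(steps) - min(steps) > .WL_TOL)
    .stopValidation("wavelengths must be evenly spaced")
  wavelengthGrid(wl[1], wl[length(wl)], mean(steps))
}

.parseHeaderMeta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Read one absorbance spectrum from a CSV file
#'
#' Expects the long dialect: two numeric columns, wavelength (nm) and
#' absorbance (AU), header \code{wavelength_nm,absorbance}. Leading comment
#' lines of the form \code{# key: value} may carry \code{timestamp},
#' \code{label} and \code{pathlength_cm} metadata; otherwise the label
#' defaults to the file name.
#'
#' @param path file path
#' @param dialect column-name convention; only \code{"long"} is a
#'   single-spectrum format (use \code{\link{readSpectrumSeries}} for wide files)
#' @return a \code{Spectrum} on its native grid
#' @seealso \code{\link{writeSpectrum}}, \code{\link{readSpectrumSeries}}
#' @export
readSpectrum <- function(path, dialect = "long") {
  if (!identical(dialect, "long"))
    .stopConfig("unknown single-spectrum dialect: ", dialect)
  if (!file.exists(path)) .stopConfig("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- .parseHeaderMeta(lines[hdr])
  dat <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"),
                         check.names = FALSE)
  if (ncol(dat) < 2L)
    .stopValidation("expected two columns (wavelength nm, absorbance AU)")
  wl <- suppressWarnings(as.numeric(dat[[1]]))
  ab <- suppressWarnings(as.numeric(dat[[2]]))
  if (any(is.na(wl)) || any(is.na(ab)))
    .stopValidation("non-numeric values in wavelength or absorbance column")
  spectrum(.gridFromWavelengths(wl), ab,
           pathlengthCm = if (!is.null(meta$pathlength_cm))
             as.numeric(meta$pathlength_cm) else 10,
           timestamp = meta$timestamp %||% "",
           label = meta$label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one spectrum to a long-dialect CSV file
#'
#' @param s a \code{Spectrum}
#' @param path output file path
#' @param digits significant digits for absorbance values (default keeps
#'   full double precision for lossless round-trips)
#' @return \code{path}, invisibly
#' @export
writeSpectrum <- function(s, path, digits = 17) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(s@timestamp)) writeLines(paste0("# timestamp: ", s@timestamp), con)
  if (nzchar(s@label)) writeLines(paste0("# label: ", s@label), con)
  writeLines(paste0("# pathlength_cm: ", format(s@pathlengthCm, digits = 15)), con)
  writeLines("wavelength_nm,absorbance", con)
  writeLines(paste(format(wavelengths(s), trim = TRUE, digits = 10),
                   format(s@absorbance, trim = TRUE, digits = digits),
                   sep = ","), con)
  invisible(path)
}

#' Read a multi-spectrum wide CSV file
#'
#' Wide dialect: first column \code{wavelength_nm}, then one absorbance
#' column per spectrum; column names become the spectrum labels (and
#' timestamps, when they parse as such for monitoring series).
#'
#' @param path file path
#' @param pathlengthCm optical path shared by all spectra (cm)
#' @return a list of \code{Spectrum}, one per data column, in file order
#' @export
readSpectrumSeries <- function(path, pathlengthCm = 10) {
  if (!file.exists(path)) .stopConfig("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- .parseHeaderMeta(lines[hdr])
  if (!is.null(meta$pathlength_cm)) pathlengthCm <- as.numeric(meta$pathlength_cm)
  dat <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"),
                         check.names = FALSE)
  if (ncol(dat) < 2L) .stopValidation("wide series needs >= 1 spectrum column")
  wl <- suppressWarnings(as.numeric(dat[[1]]))
  if (any(is.na(wl))) .stopValidation("non-numeric wavelength column")
  grid <- .gridFromWavelengths(wl)
  labs <- colnames(dat)[-1]
  lapply(seq_along(labs), function(j) {
    ab <- suppressWarnings(as.numeric(dat[[j + 1L]]))
    if (any(is.na(ab)))
      .stopValidation("non-numeric absorbance values in column '", labs[j], "'")
    spectrum(grid, ab, pathlengthCm = pathlengthCm,
             timestamp = labs[j], label = labs[j])
  })
}

#' Write a list of spectra as a wide CSV file
#'
#' Column names are the spectra labels (falling back to timestamps, then
#' \code{s1, s2, ...}). All spectra must share one grid and pathlength.
#'
#' @param spectra list of \code{Spectrum} on a common grid
#' @param path output file path
#' @param digits significant digits for absorbance values
#' @return \code{path}, invisibly
#' @export
writeSpectrumSeries <- function(spectra, path, digits = 17) {
  if (!length(spectra)) .stopValidation("empty spectra list")
  g <- spectra[[1]]@grid
  pl <- spectra[[1]]@pathlengthCm
  for (s in spectra) {
    if (!.sameGrid(s@grid, g)) .stopValidation("spectra are not on a common grid")
    if (abs(s@pathlengthCm - pl) > .WL_TOL)
      .stopValidation("spectra have differing pathlengths")
  }
  labs <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (nzchar(s@label)) s@label
    else if (nzchar(s@timestamp)) s@timestamp
    else paste0("s", i)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pathlength_cm: ", format(pl, digits = 15)), con)
  writeLines(paste(c("wavelength_nm", labs), collapse = ","), con)
  mat <- vapply(spectra, function(s) s@absorbance, numeric(length(g)))
  rows <- cbind(format(wavelengths(g), trim = TRUE, digits = 10),
                apply(mat, 2, format, trim = TRUE, digits = digits))
  writeLines(apply(rows, 1, paste, collapse = ","), con)
  invisible(path)
}
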
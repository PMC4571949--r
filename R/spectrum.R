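#' Spectrum objects
#'
#' A `spectrum` is the package's working container for any wavelength-indexed
#' measurement: a relative spectral sensitivity, a relative absorbance, or a
#' difference absorbance (M-form minus R-form).  Wavelengths are in nm and
#' must be strictly increasing and positive; sensitivity and absorbance
#' values must be finite and non-negative, difference values may take any
#' sign.
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly
#'   increasing, all positive, length >= 2.
#' @param value numeric vector of the same length as `wavelength`.
#' @param kind one of `"sensitivity"`, `"absorbance"`, `"difference"`.
#' @param label free-text label carried through resampling and plotting.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength`, `value`, `kind` and `label`.
#' @examples
#' s <- spectrum(400:410, seq(0, 1, length.out = 11), kind = "absorbance")
#' s
#' @export
spectrum <- function(wavelength, value,
                     kind = c("sensitivity", "absorbance", "difference"),
                     label = "") {
  kind <- match.arg(kind)
  x <- structure(
    list(wavelength = as.numeric(wavelength), value = as.numeric(value),
         kind = kind, label = as.character(label)[1]),
    class = "spectrum")
  validate_spectrum(x)
}

validate_spectrum <- function(x) {
  wl <- x$wavelength
  v <- x$value
  if (length(wl) != length(v))
    stop("wavelength and value must have equal length", call. = FALSE)
  if (length(wl) < 2)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(wl) || any(!is.finite(wl)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(wl <= 0))
    stop("wavelengths must be positive (nm)", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(v)))
    stop("values must be finite", call. = FALSE)
  if (x$kind %in% c("sensitivity", "absorbance") && any(v < 0))
    stop(x$kind, " values must be non-negative", call. = FALSE)
  x
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum kind=%s n=%d range=%g-%g nm%s>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              if (nzchar(x$label)) paste0(" label=", x$label) else ""))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength = x$wavelength, value = x$value)
}

#' Canonical wavelength grid
#'
#' The default working grid, 300-700 nm in 1-nm steps, spans the UV
#' sensitizing-pigment peak through the long-wavelength tail of the M-form.
#'
#' @param min,max grid bounds in nm.
#' @param step grid step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(min = 300, max = 700, step = 1) {
  if (step <= 0 || max <= min) stop("invalid grid specification", call. = FALSE)
  seq(min, max, by = step)
}

#' Read a two-column spectrum file
#'
#' Reads a tab- or comma-delimited file with wavelength (nm) in the first
#' column and the measured value in the second.  The delimiter is detected
#' automatically; lines starting with `#` are skipped.  Files with more or
#' fewer than two columns are rejected rather than silently subset.
#'
#' @param path path to a TSV/CSV file.
#' @param kind spectrum kind to validate against, see [spectrum()].
#' @param label optional label; defaults to the file name.
#' @return A validated [spectrum()].
#' @export
read_spectrum <- function(path,
                          kind = c("sensitivity", "absorbance", "difference"),
                          label = basename(path)) {
  kind <- match.arg(kind)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 2)
    stop("spectrum file needs at least 2 data rows: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol != 2))
    stop(sprintf("expected 2 columns but found %d on line %d of %s",
                 ncol[ncol != 2][1], lineno[ncol != 2][1], path),
         call. = FALSE)
  m <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
  suppressWarnings(num <- matrix(as.numeric(m), ncol = 2))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("non-numeric value on line %d of %s", lineno[bad], path),
         call. = FALSE)
  }
  spectrum(num[, 1], num[, 2], kind = kind, label = label)
}

#' Write a spectrum to a delimited file
#'
#' Values are written in full precision so a read/write cycle round-trips
#' bit-identically.
#'
#' @param x a [spectrum()].
#' @param path output file path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "spectrum"))
  lines <- paste(sprintf("%.17g", x$wavelength),
                 sprintf("%.17g", x$value), sep = sep)
  writeLines(c(paste0("# kind=", x$kind, " label=", x$label), lines), path)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`.  Extrapolation is never performed:
#' every grid point must lie inside the spectrum's wavelength range, and
#' callers are expected to clip fitting windows to the data range.
#'
#' @param x a [spectrum()].
#' @param grid strictly increasing wavelengths (nm) inside the range of
#'   `x$wavelength`.
#' @return A [spectrum()] on `grid` with the same kind and label.
#' @export
resample <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points", call. = FALSE)
  if (min(grid) < min(x$wavelength) || max(grid) > max(x$wavelength))
    stop("grid extends outside the spectrum range; no extrapolation",
         call. = FALSE)
  v <- stats::approx(x$wavelength, x$value, xout = grid, method = "linear",
                     ties = "ordered")$y
  out <- structure(list(wavelength = grid, value = v, kind = x$kind,
                        label = x$label), class = "spectrum")
  # difference spectra may interpolate through 0; skip sign re-validation
  out
}

# Restrict a spectrum to a closed wavelength window.  Internal.
spectrum_window <- function(x, window) {
  stopifnot(inherits(x, "spectrum"), length(window) == 2)
  if (window[1] >= window[2]) stop("window must be (lo, hi)", call. = FALSE)
  keep <- x$wavelength >= window[1] & x$wavelength <= window[2]
  structure(list(wavelength = x$wavelength[keep], value = x$value[keep],
                 kind = x$kind, label = x$label), class = "spectrum")
}
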
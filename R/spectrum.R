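#' One-dimensional Raman spectrum
#'
#' Container for a sampled Raman shift/intensity curve with free-form
#' acquisition metadata. This is the unit every stage of the package consumes
#' and produces: band intensities (I750, I1127, I1358, I1377, ...) and the
#' whole-spectrum sum are all read from objects of this class.
#'
#' @param shifts Numeric vector of Raman shifts (cm^-1), strictly increasing,
#'   all within 100-4000 cm^-1.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `shifts`, all finite. Negative values are permitted (they arise
#'   after baseline subtraction).
#' @param meta Named list of acquisition metadata (excitation wavelength,
#'   collection time, condition label, ...).
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shifts, intensities, meta = list()) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  x <- structure(
    list(shifts = shifts, intensities = intensities, meta = meta),
    class = "raman_spectrum"
  )
  validate_spectrum(x)
  x
}

#' Validate a Raman spectrum's invariants
#'
#' @param x A `raman_spectrum`.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `ramanredox_validation_error`.
#' @export
validate_spectrum <- function(x) {
  if (!inherits(x, "raman_spectrum")) {
    stop_ramanredox("not a raman_spectrum object", "ramanredox_validation_error")
  }
  s <- x$shifts
  y <- x$intensities
  if (length(s) < 2 || length(s) != length(y)) {
    stop_ramanredox("shifts and intensities must have equal length >= 2",
                    "ramanredox_validation_error")
  }
  if (anyNA(s) || any(!is.finite(s)) || any(!is.finite(y))) {
    stop_ramanredox("shifts and intensities must be finite",
                    "ramanredox_validation_error")
  }
  if (any(diff(s) <= 0)) {
    stop_ramanredox("shifts must be strictly increasing (duplicated or non-monotone shifts)",
                    "ramanredox_validation_error")
  }
  if (min(s) < 100 || max(s) > 4000) {
    stop_ramanredox("shifts must lie within [100, 4000] cm^-1",
                    "ramanredox_validation_error")
  }
  if (!is.list(x$meta)) {
    stop_ramanredox("meta must be a list", "ramanredox_validation_error")
  }
  invisible(x)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$shifts)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$shifts), rng[1], rng[2]))
  cat(sprintf("  intensity range: [%.4g, %.4g] a.u.\n",
              min(x$intensities), max(x$intensities)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$shifts, x$intensities, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", ...)
}

#' Resample a spectrum onto a new shift grid
#'
#' Linear interpolation onto `grid`; no extrapolation is performed, so the
#' grid must lie within the spectrum's shift range. Grid points that coincide
#' with input shifts reproduce the input intensities exactly.
#'
#' @param x A `raman_spectrum`.
#' @param grid Strictly increasing numeric vector of target shifts (cm^-1).
#' @return A `raman_spectrum` sampled at `grid` (metadata carried over).
#' @export
resample_spectrum <- function(x, grid) {
  validate_spectrum(x)
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop_ramanredox("grid must be strictly increasing with length >= 2",
                    "ramanredox_validation_error")
  }
  if (min(grid) < min(x$shifts) || max(grid) > max(x$shifts)) {
    stop_ramanredox("grid extends outside the spectrum's shift range (no extrapolation)",
                    "ramanredox_range_error")
  }
  y <- stats::approx(x$shifts, x$intensities, xout = grid, method = "linear")$y
  raman_spectrum(grid, y, x$meta)
}

## scale every intensity; used by scale-invariance property tests
scale_spectrum <- function(x, c) {
  raman_spectrum(x$shifts, x$intensities * c, x$meta)
}
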
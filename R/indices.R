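#' Sum-normalized band intensity
#'
#' Expresses a band amplitude relative to the summed intensity of the whole
#' baseline-corrected spectrum, making acquisitions with different optical
#' throughput comparable. Invariant under global intensity scaling.
#'
#' @inheritParams band_amplitude
#' @param range Shift interval for the intensity sum (default 520-1750 cm^-1).
#' @return Dimensionless ratio in `[0, 1]`.
#' @export
normalized_intensity <- function(spectrum, band, range = c(520, 1750),
                                 mode = c("height", "fit"),
                                 library = default_band_library()) {
  mode <- match.arg(mode)
  isum <- total_intensity(spectrum, range)
  if (isum <= 0) {
    stop_ramanredox("total intensity is not positive; normalized intensity undefined",
                    "ramanredox_ratio_error")
  }
  amp <- band_amplitude(spectrum, band, mode = mode, library = library)
  min(amp / isum, 1)
}

#' c-type to b-type cytochrome redox ratio
#'
#' The ratio of the 750 cm^-1 amplitude (dominated by reduced cytochromes c
#' and c1) to the 1127 cm^-1 amplitude (dominated by reduced b-type
#' cytochromes) estimates the relative amount of reduced c-type vs b-type
#' cytochromes. Scale-invariant.
#'
#' @inheritParams band_amplitude
#' @return Non-negative dimensionless ratio.
#' @export
c_to_b_ratio <- function(spectrum, mode = c("height", "fit"),
                         library = default_band_library()) {
  mode <- match.arg(mode)
  i750 <- band_amplitude(spectrum, 750, mode = mode, library = library)
  i1127 <- band_amplitude(spectrum, 1127, mode = mode, library = library)
  if (i1127 <= 0) {
    stop_ramanredox("zero 1127 cm^-1 amplitude; redox ratio undefined",
                    "ramanredox_ratio_error")
  }
  i750 / i1127
}

#' nu4 scattering-efficiency calibration constant
#'
#' Holds the empirical ratio q of nu4 peak scattering intensity of fully
#' oxygenated myoglobin (1377 cm^-1) to fully deoxygenated myoglobin
#' (1358 cm^-1) at matched concentration, with its standard error and the
#' number of calibration experiments. The shipped default is q = 1.55,
#' se = 0.10, n = 3.
#'
#' @param q Positive ratio.
#' @param se Non-negative standard error.
#' @param n Number of calibration experiments (>= 1).
#' @return An object of class `calibration_constant`.
#' @export
calibration_constant <- function(q = 1.55, se = 0.10, n = 3L) {
  if (!is.numeric(q) || q <= 0) {
    stop_ramanredox("q must be positive", "ramanredox_validation_error")
  }
  if (!is.numeric(se) || se < 0) {
    stop_ramanredox("se must be non-negative", "ramanredox_validation_error")
  }
  if (!is.numeric(n) || n < 1) {
    stop_ramanredox("n must be >= 1", "ramanredox_validation_error")
  }
  structure(list(q = q, se = se, n = as.integer(n)), class = "calibration_constant")
}

#' @export
print.calibration_constant <- function(x, ...) {
  cat(sprintf("<calibration_constant> q = %.4g +/- %.2g (SE), n = %d\n",
              x$q, x$se, x$n))
  invisible(x)
}

#' Calibrate the nu4 oxy/deoxy scattering-efficiency ratio
#'
#' Computes q = I1377(oxy) / I1358(fully reduced), each intensity
#' sum-normalized within its own spectrum before ratioing so that spectra
#' from different hearts are comparable. With equally many spectra per group
#' the experiments are treated as paired (ratio per pair, mean +/- SE over
#' pairs); otherwise the ratio of group means is used with a delta-method SE.
#'
#' @param oxy_spectra List of baseline-corrected spectra of hearts with fully
#'   oxygenated Mb.
#' @param reduced_spectra List of baseline-corrected spectra of
#'   dithionite-treated (fully deoxygenated) hearts.
#' @param oxy_band,red_band Bands quantified in each group (defaults: the
#'   nu4 markers at 1377 and 1358 cm^-1).
#' @param range Sum-normalization interval.
#' @param mode Quantification mode passed to [band_amplitude()]; the default
#'   `"fit"` resolves the 1358/1377 overlap.
#' @param library Band library.
#' @return A [calibration_constant()].
#' @export
calibrate_q <- function(oxy_spectra, reduced_spectra,
                        oxy_band = 1377, red_band = 1358,
                        range = c(520, 1750), mode = c("fit", "height"),
                        library = default_band_library()) {
  mode <- match.arg(mode)
  if (inherits(oxy_spectra, "raman_spectrum")) oxy_spectra <- list(oxy_spectra)
  if (inherits(reduced_spectra, "raman_spectrum")) reduced_spectra <- list(reduced_spectra)
  if (!length(oxy_spectra) || !length(reduced_spectra)) {
    stop_ramanredox("need at least one spectrum per calibration group",
                    "ramanredox_validation_error")
  }
  norm_at <- function(sp, band, who) {
    v <- normalized_intensity(sp, band, range = range, mode = mode,
                              library = library)
    if (v <= 0) {
      stop_ramanredox(
        sprintf("zero nu4 intensity in %s calibration spectrum (%s)",
                who, sp$meta$condition %||% "unlabelled"),
        "ramanredox_calibration_error"
      )
    }
    v
  }
  o <- vapply(oxy_spectra, norm_at, numeric(1), band = oxy_band, who = "oxygenated")
  r <- vapply(reduced_spectra, norm_at, numeric(1), band = red_band, who = "reduced")
  if (length(o) == length(r)) {
    ratios <- o / r
    q <- mean(ratios)
    se <- if (length(ratios) > 1) stats::sd(ratios) / sqrt(length(ratios)) else 0
    n <- length(ratios)
  } else {
    q <- mean(o) / mean(r)
    vo <- if (length(o) > 1) stats::var(o) / length(o) else 0
    vr <- if (length(r) > 1) stats::var(r) / length(r) else 0
    se <- q * sqrt(vo / mean(o)^2 + vr / mean(r)^2)
    n <- min(length(o), length(r))
  }
  calibration_constant(q = q, se = se, n = n)
}

#' Deoxymyoglobin fraction from nu4 band intensities
#'
#' Estimates the fraction of deoxygenated myoglobin from the dMb (1358 cm^-1)
#' and oMb (1377 cm^-1) nu4 amplitudes, correcting for the difference in
#' scattering efficiency with the calibration constant q:
#' `f = q * I1358 / (q * I1358 + I1377)`. By construction of q, equal true
#' concentrations of oMb and dMb give f = 0.5; f is monotone increasing in
#' `i_1358` and decreasing in `i_1377`.
#'
#' @param i_1358 Non-negative dMb nu4 intensity (raw or sum-normalized;
#'   the ratio is scale-invariant provided both intensities share a scale).
#' @param i_1377 Non-negative oMb nu4 intensity on the same scale.
#' @param q A [calibration_constant()] or a positive number.
#' @return Fraction in `[0, 1]` (vectorized over the intensities).
#' @export
dmb_fraction <- function(i_1358, i_1377, q = calibration_constant()) {
  if (inherits(q, "calibration_constant")) q <- q$q
  if (!is.numeric(q) || q <= 0) {
    stop_ramanredox("q must be positive", "ramanredox_validation_error")
  }
  if (any(i_1358 < 0) || any(i_1377 < 0)) {
    stop_ramanredox("nu4 intensities must be non-negative",
                    "ramanredox_validation_error")
  }
  if (any(i_1358 + i_1377 == 0)) {
    stop_ramanredox("both nu4 intensities are zero; fraction undefined",
                    "ramanredox_ratio_error")
  }
  q * i_1358 / (q * i_1358 + i_1377)
}

#' Percent-of-control series
#'
#' Maps per-condition values to percent of the control mean (control itself
#' maps to a mean of exactly 100).
#'
#' @param values Numeric vector of per-condition scalars.
#' @param control Control value(s); a vector is averaged.
#' @return `100 * values / mean(control)`.
#' @export
percent_of_control <- function(values, control) {
  ctrl <- mean(as.numeric(control))
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop_ramanredox("control mean must be positive", "ramanredox_ratio_error")
  }
  100 * as.numeric(values) / ctrl
}

#' Per-spectrum redox and oxygenation indices
#'
#' Computes the derived quantities for one baseline-corrected spectrum:
#' sum-normalized intensities of the six marker bands (604, 750, 1127, 1337,
#' 1358, 1377 cm^-1), the c-type/b-type redox ratio I750/I1127, and the
#' calibrated deoxymyoglobin fraction.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param library Band library.
#' @param q A [calibration_constant()] or positive number.
#' @param range Sum-normalization interval.
#' @param mode Quantification mode (default `"fit"`: joint non-negative
#'   decomposition per overlap cluster, robust to band overlap and noise).
#' @return A one-row data.frame with columns `norm_604`, `norm_750`,
#'   `norm_1127`, `norm_1337`, `norm_1358`, `norm_1377`, `ratio_c_b`,
#'   `f_dmb`, `i_sum`.
#' @export
spectrum_indices <- function(spectrum, library = default_band_library(),
                             q = calibration_constant(), range = c(520, 1750),
                             mode = c("fit", "height")) {
  mode <- match.arg(mode)
  isum <- total_intensity(spectrum, range)
  if (isum <= 0) {
    stop_ramanredox("total intensity is not positive", "ramanredox_ratio_error")
  }
  amps <- quantify_bands(spectrum, library, mode = mode)
  amp_at <- function(center) {
    i <- which(abs(library$center - center) < 0.5)
    if (length(i) != 1) {
      stop_ramanredox(sprintf("library lacks a band at %g cm^-1", center),
                      "ramanredox_validation_error")
    }
    unname(amps[i])
  }
  a604 <- amp_at(604); a750 <- amp_at(750); a1127 <- amp_at(1127)
  a1337 <- amp_at(1337); a1358 <- amp_at(1358); a1377 <- amp_at(1377)
  data.frame(
    norm_604 = a604 / isum, norm_750 = a750 / isum, norm_1127 = a1127 / isum,
    norm_1337 = a1337 / isum, norm_1358 = a1358 / isum, norm_1377 = a1377 / isum,
    ## a noise-floor 1127 estimate of zero leaves the redox ratio undefined
    ## for that spectrum; reported as NA rather than aborting a whole run
    ratio_c_b = if (a1127 > 0) a750 / a1127 else NA_real_,
    f_dmb = if (a1358 + a1377 > 0) dmb_fraction(a1358, a1377, q) else NA_real_,
    i_sum = isum
  )
}
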
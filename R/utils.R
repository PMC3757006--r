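#' @keywords internal
"_PACKAGE"

#' Lorentzian line profile
#'
#' Evaluates an amplitude-parameterized Lorentzian, the canonical line shape
#' for heme resonance Raman bands.
#'
#' @param x Raman shifts (cm^-1) at which to evaluate.
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1).
#' @param amplitude Peak height at `center`.
#' @return Numeric vector of intensities.
#' @export
lorentzian <- function(x, center, fwhm, amplitude = 1) {
  stopifnot(is.numeric(x), fwhm > 0)
  g <- fwhm / 2
  amplitude * g^2 / (g^2 + (x - center)^2)
}

## deterministic per-replicate seed derivation; keeps seeds in 32-bit range
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ramanredox <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ramanredox_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
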
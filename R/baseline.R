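#' Baseline-correction settings
#'
#' Configuration for the asymmetric-least-squares (ALS) fluorescence baseline
#' estimator. The estimator fits a smooth curve by iteratively reweighted
#' penalized least squares: points whose residual exceeds twice the robust
#' background scale (band candidates) get weight `asymmetry`, background
#' points get weight 1, and a second-difference penalty scaled by
#' `smoothness` keeps the curve free of curvature at band scale, bridging
#' the down-weighted band regions from below.
#'
#' @param method Baseline algorithm identifier; only `"als"` is implemented.
#' @param smoothness Positive regularization scalar (penalty on squared
#'   second differences). Larger values give stiffer baselines; the default
#'   1e7 suppresses curvature on the ~15 cm^-1 scale of heme bands while
#'   following a slowly decaying fluorescence background.
#' @param asymmetry Weight given to points flagged as band signal, in (0, 1).
#'   Small values hug the background beneath the bands.
#' @param max_iter Maximum reweighting iterations.
#' @param presmooth Odd Savitzky-Golay window (points) used to smooth the
#'   spectrum before estimating the baseline (the baseline is still
#'   subtracted from the raw spectrum). Set to 0 to disable. Smoothing keeps
#'   detector noise from dragging the lower-envelope fit downward.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = "als", smoothness = 1e7, asymmetry = 0.001,
                            max_iter = 50L, presmooth = 11L) {
  if (!identical(method, "als")) {
    stop_ramanredox(sprintf("unknown baseline method '%s'", method),
                    "ramanredox_validation_error")
  }
  if (!is.numeric(smoothness) || smoothness <= 0) {
    stop_ramanredox("smoothness must be positive", "ramanredox_validation_error")
  }
  if (!is.numeric(asymmetry) || asymmetry <= 0 || asymmetry >= 1) {
    stop_ramanredox("asymmetry must lie in (0, 1)", "ramanredox_validation_error")
  }
  if (!is.numeric(max_iter) || max_iter < 1) {
    stop_ramanredox("max_iter must be a positive integer", "ramanredox_validation_error")
  }
  if (!is.numeric(presmooth) || presmooth < 0 ||
      (presmooth > 0 && (presmooth %% 2 != 1 || presmooth < 5))) {
    stop_ramanredox("presmooth must be 0 or an odd integer >= 5",
                    "ramanredox_validation_error")
  }
  structure(
    list(method = method, smoothness = smoothness, asymmetry = asymmetry,
         max_iter = as.integer(max_iter), presmooth = as.integer(presmooth)),
    class = "baseline_config"
  )
}

## Adaptive asymmetric least squares (Whittaker smoother with iteratively
## reweighted band suppression). Points whose residual exceeds twice the
## robust background scale are treated as band signal and downweighted to
## `p`; the second-difference penalty bridges the suppressed regions, so
## the baseline passes beneath bands instead of climbing into them.
als_fit <- function(y, lambda, p, max_iter) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  it <- 0L
  yscale <- max(abs(y), 1e-12)
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + P, w * y))
    delta <- max(abs(z_new - z)) / yscale
    z <- z_new
    r <- y - z
    background <- w >= 0.5
    sigma <- stats::mad(r[background], center = 0)
    ## band threshold: 2x the robust background scale plus an absolute floor
    ## of 0.5% of the intensity range, so the small smooth residual a stiff
    ## smoother leaves on a curved but band-free background is not mistaken
    ## for band signal
    thresh <- 2 * sigma + 0.005 * diff(range(y))
    if (!is.finite(thresh) || thresh <= 0) {
      w_new <- rep(1, n)
    } else {
      w_new <- ifelse(r > thresh, p, 1)
    }
    if ((delta < 1e-8 && all(w_new == w)) || all(w_new == w)) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  list(baseline = z, iterations = it, converged = converged)
}

#' Subtract the fluorescence baseline from a spectrum
#'
#' Estimates a smooth baseline with asymmetric least squares (optionally on a
#' Savitzky-Golay presmoothed copy) and subtracts it pointwise from the raw
#' intensities.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [baseline_config()].
#' @return A list with elements `corrected` (the baseline-subtracted
#'   [raman_spectrum()]; may contain negative values) and `baseline` (the
#'   estimated baseline as a [raman_spectrum()]). `corrected$intensities +
#'   baseline$intensities` reproduces the input exactly.
#' @export
subtract_baseline <- function(spectrum, config = baseline_config()) {
  validate_spectrum(spectrum)
  stopifnot(inherits(config, "baseline_config"))
  y <- spectrum$intensities
  y_est <- y
  if (config$presmooth > 0 && length(y) > config$presmooth) {
    y_est <- signal::sgolayfilt(y, p = 2, n = config$presmooth)
  }
  fit <- als_fit(y_est, config$smoothness, config$asymmetry, config$max_iter)
  if (!fit$converged) {
    stop_ramanredox(
      sprintf("ALS baseline did not converge within %d iterations", fit$iterations),
      "ramanredox_convergence_error",
      iterations = fit$iterations
    )
  }
  corrected <- raman_spectrum(spectrum$shifts, y - fit$baseline, spectrum$meta)
  baseline <- raman_spectrum(spectrum$shifts, fit$baseline, spectrum$meta)
  list(corrected = corrected, baseline = baseline)
}
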
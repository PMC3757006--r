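# shared fixtures: everything is generated in code at test time

corr_default <- function(sp) subtract_baseline(sp)$corrected

# baseline-free spectrum assembled from explicit Lorentzians
lorentz_spectrum <- function(grid, centers, amps, fwhm = 14) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + lorentzian(grid, centers[i], fwhm, amps[i])
  }
  raman_spectrum(grid, y)
}

# cubic fluorescence-like background used by the baseline oracles
cubic_background <- function(grid, amp = 5) {
  t <- (grid - min(grid)) / diff(range(grid))
  amp * (1 - 0.8 * t + 0.3 * t^2 - 0.05 * t^3)
}

noise_free_state <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0), list(...))
  do.call(physiological_state, args)
}
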
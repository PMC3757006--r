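#' Default simulation grid
#'
#' 520-1750 cm^-1 at 1 cm^-1 steps: covers every band in the default library
#' at typical dispersive-spectrometer resolution.
#'
#' @return Numeric vector of Raman shifts.
#' @export
default_grid <- function() {
  seq(520, 1750, by = 1)
}

#' Pure-component emission profiles
#'
#' Relative Lorentzian band amplitudes for each scattering species at 532 nm
#' excitation. Reduced c-type cytochromes carry 604 (unique), 750 (dominant),
#' 1310 and 1582 cm^-1 with a minor 1127 contribution; reduced b-type
#' cytochromes mirror this with 1127 dominant plus 1300 and 1337 (unique);
#' oMb scatters at 1377 (nu4), 1587 and 1640 cm^-1, dMb at the downshifted
#' 1358, 1556 and 1606 cm^-1 positions. Oxidized cytochromes contribute
#' negligibly at 532 nm and are represented by an all-zero profile. The
#' broad 1658 cm^-1 amide I profile stands for the aggregate non-heme
#' protein scatter.
#'
#' Within-profile amplitudes are configurable constants, not measured
#' quantities; the defaults keep 750 cm^-1 c-type-dominated and 1127 cm^-1
#' b-type-dominated, and give oMb and dMb equal relative nu4 amplitudes so
#' that the whole-profile efficiency ratio q_true carries the oxy/deoxy
#' scattering difference.
#'
#' @return Named list of data.frames with columns `center`, `rel_amp`,
#'   `fwhm`.
#' @export
component_profiles <- function() {
  list(
    cyt_c_red = data.frame(
      center = c(604, 750, 1127, 1310, 1582),
      rel_amp = c(0.15, 1.00, 0.05, 0.30, 0.80),
      fwhm = 14
    ),
    cyt_b_red = data.frame(
      center = c(750, 1127, 1300, 1337, 1582),
      rel_amp = c(0.05, 1.00, 0.30, 0.50, 0.80),
      fwhm = 14
    ),
    cyt_ox = data.frame(center = numeric(0), rel_amp = numeric(0),
                        fwhm = numeric(0)),
    oMb = data.frame(
      center = c(1377, 1587, 1640),
      rel_amp = c(0.35, 1.00, 0.55),
      fwhm = 14
    ),
    dMb = data.frame(
      center = c(1358, 1556, 1606),
      rel_amp = c(0.35, 1.00, 0.55),
      fwhm = 14
    ),
    amide_I = data.frame(center = 1658, rel_amp = 1.00, fwhm = 25)
  )
}

#' Spectrum of a pure component
#'
#' Sum of the profile's Lorentzians, rescaled so the maximum sampled
#' intensity is exactly 1 (an empty profile gives an all-zero spectrum).
#'
#' @param profile A profile data.frame (`center`, `rel_amp`, `fwhm`), e.g.
#'   one element of [component_profiles()].
#' @param grid Shift grid (cm^-1).
#' @return A [raman_spectrum()].
#' @export
component_spectrum <- function(profile, grid = default_grid()) {
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop_ramanredox("grid must be strictly increasing", "ramanredox_validation_error")
  }
  y <- numeric(length(grid))
  for (i in seq_len(nrow(profile))) {
    y <- y + lorentzian(grid, profile$center[i], profile$fwhm[i],
                        profile$rel_amp[i])
  }
  m <- max(y)
  if (m > 0) y <- y / m
  raman_spectrum(grid, y)
}

## peak normalization factor of a profile on a grid (max of the raw sum);
## needed to convert mixing coefficients into per-band Lorentzian amplitudes
profile_norm_factor <- function(profile, grid) {
  if (!nrow(profile)) return(1)
  y <- numeric(length(grid))
  for (i in seq_len(nrow(profile))) {
    y <- y + lorentzian(grid, profile$center[i], profile$fwhm[i],
                        profile$rel_amp[i])
  }
  max(y)
}

#' Ground-truth physiological state of the simulator
#'
#' Describes the composition of a simulated heart spectrum: myoglobin
#' deoxygenation fraction, reduced fractions of the c- and b-type cytochrome
#' pools, abundance scalars, the true nu4 oxy/deoxy scattering-efficiency
#' ratio, fluorescence baseline magnitude and detector noise.
#'
#' @param f_dmb Fraction of myoglobin deoxygenated, in `[0, 1]`.
#' @param r_c Fraction of c-type cytochromes reduced, in `[0, 1]`.
#' @param r_b Fraction of b-type cytochromes reduced, in `[0, 1]`.
#' @param mb_scale,cyt_scale Positive abundance scalars for the myoglobin
#'   and cytochrome pools.
#' @param q_true True oMb/dMb scattering-efficiency ratio (> 0); multiplies
#'   the whole oMb profile.
#' @param baseline_amp Fluorescence baseline intensity at the low-shift edge
#'   (a.u., >= 0).
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   strongest noise-free band intensity (>= 0).
#' @param amide_amp Amplitude of the broad non-heme protein band (>= 0).
#' @return An object of class `physiological_state`.
#' @export
physiological_state <- function(f_dmb = 0.05, r_c = 0.4, r_b = 0.4,
                                mb_scale = 1, cyt_scale = 0.29,
                                q_true = 1.55, baseline_amp = 3,
                                noise_sd = 0.02, amide_amp = 4.0) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_ramanredox(sprintf("%s must lie in [0, 1]", nm),
                      "ramanredox_validation_error")
    }
  }
  chk01(f_dmb, "f_dmb"); chk01(r_c, "r_c"); chk01(r_b, "r_b")
  if (mb_scale <= 0 || cyt_scale <= 0 || q_true <= 0) {
    stop_ramanredox("mb_scale, cyt_scale and q_true must be positive",
                    "ramanredox_validation_error")
  }
  if (baseline_amp < 0 || noise_sd < 0 || amide_amp < 0) {
    stop_ramanredox("baseline_amp, noise_sd and amide_amp must be non-negative",
                    "ramanredox_validation_error")
  }
  structure(
    list(f_dmb = f_dmb, r_c = r_c, r_b = r_b, mb_scale = mb_scale,
         cyt_scale = cyt_scale, q_true = q_true, baseline_amp = baseline_amp,
         noise_sd = noise_sd, amide_amp = amide_amp),
    class = "physiological_state"
  )
}

## smooth positive decreasing cubic, fluorescence-like; t in [0, 1]
baseline_shape <- function(t) {
  1 - 0.9 * t + 0.35 * t^2 - 0.08 * t^3
}

#' Simulate one heart Raman spectrum with known ground truth
#'
#' Generates
#' `baseline + mb_scale * ((1 - f_dmb) * q_true * oMb + f_dmb * dMb)
#'  + cyt_scale * (r_c * cytC + r_b * cytB) + amide_amp * amideI + noise`
#' on the given grid, with each component profile peak-normalized to 1 and
#' additive Gaussian noise scaled to the strongest noise-free band.
#' Identical `(state, seed)` pairs give bit-identical spectra.
#'
#' @param state A [physiological_state()].
#' @param grid Shift grid (cm^-1).
#' @param seed Integer seed for the noise draw.
#' @return A list with `spectrum` (the raw simulated [raman_spectrum()]) and
#'   `truth` (list: the state, per-band true Lorentzian amplitudes named by
#'   the default library's band names, the noise-free signal sum `i_sum`,
#'   the absolute noise sd, and the seed).
#' @export
synth_heart_spectrum <- function(state, grid = default_grid(), seed = 1L) {
  stopifnot(inherits(state, "physiological_state"))
  grid <- as.numeric(grid)
  profiles <- component_profiles()
  coefs <- c(
    cyt_c_red = state$cyt_scale * state$r_c,
    cyt_b_red = state$cyt_scale * state$r_b,
    cyt_ox = 0,
    oMb = state$mb_scale * (1 - state$f_dmb) * state$q_true,
    dMb = state$mb_scale * state$f_dmb,
    amide_I = state$amide_amp
  )
  signal <- numeric(length(grid))
  heme_signal <- numeric(length(grid))
  band_amps <- numeric(0)
  for (nm in names(profiles)) {
    pf <- profiles[[nm]]
    if (!nrow(pf) || coefs[[nm]] == 0) {
      if (nrow(pf)) {
        a <- rep(0, nrow(pf)); names(a) <- paste0(nm, "_", pf$center)
        band_amps <- c(band_amps, a)
      }
      next
    }
    nf <- profile_norm_factor(pf, grid)
    a <- coefs[[nm]] * pf$rel_amp / nf
    names(a) <- paste0(nm, "_", pf$center)
    band_amps <- c(band_amps, a)
    for (i in seq_len(nrow(pf))) {
      contrib <- lorentzian(grid, pf$center[i], pf$fwhm[i], a[i])
      signal <- signal + contrib
      if (nm != "amide_I") heme_signal <- heme_signal + contrib
    }
  }
  tt <- (grid - min(grid)) / (max(grid) - min(grid))
  baseline <- state$baseline_amp * baseline_shape(tt)
  ## noise is referenced to the strongest heme band, not the broad non-heme
  ## envelope, so marker signal-to-noise is independent of the envelope size
  ref <- if (any(heme_signal > 0)) max(heme_signal) else max(signal)
  sd_abs <- state$noise_sd * ref
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(grid), sd = sd_abs))
  spectrum <- raman_spectrum(
    grid, signal + baseline + noise,
    meta = list(excitation_nm = 532, seed = as.integer(seed))
  )
  ## aggregate per-center amplitudes (750, 1127, 1582 receive both cyt types)
  centers <- as.numeric(sub(".*_", "", names(band_amps)))
  truth_amps <- tapply(band_amps, centers, sum)
  list(
    spectrum = spectrum,
    truth = list(state = state, band_amplitudes = truth_amps,
                 i_sum = sum(signal), noise_sd_abs = sd_abs,
                 seed = as.integer(seed))
  )
}

#' Experimental scenario
#'
#' An ordered series of labelled physiological states with replicate counts,
#' mirroring one perfused-heart experiment time course.
#'
#' @param name Scenario name.
#' @param timepoints List of timepoints, each a list with `label`,
#'   `state` (a [physiological_state()]) and `n_replicates` (>= 1).
#' @return An object of class `raman_scenario`.
#' @export
scenario <- function(name, timepoints) {
  if (!length(timepoints)) {
    stop_ramanredox("scenario needs at least one timepoint",
                    "ramanredox_validation_error")
  }
  for (tp in timepoints) {
    if (is.null(tp$label) || !inherits(tp$state, "physiological_state") ||
        is.null(tp$n_replicates) || tp$n_replicates < 1) {
      stop_ramanredox("each timepoint needs label, state and n_replicates >= 1",
                      "ramanredox_validation_error")
    }
  }
  structure(list(name = name, timepoints = timepoints), class = "raman_scenario")
}

## solve FCCP reduced-fraction multipliers so that the sum-normalized 750 and
## 1127 intensities hit the stated percent-of-control targets (noise-free
## fixed point on the generator's linear amplitude model)
solve_fccp_state <- function(target_750_pct, target_1127_pct,
                             control = physiological_state(),
                             grid = default_grid()) {
  profiles <- component_profiles()
  nf_c <- profile_norm_factor(profiles$cyt_c_red, grid)
  nf_b <- profile_norm_factor(profiles$cyt_b_red, grid)
  amp_unit <- function(pf, nf, center) {
    i <- which(pf$center == center)
    if (length(i)) pf$rel_amp[i] / nf else 0
  }
  ## per-unit-(cyt_scale * r) amplitudes and grid-summed intensities
  u <- matrix(c(
    amp_unit(profiles$cyt_c_red, nf_c, 750), amp_unit(profiles$cyt_b_red, nf_b, 750),
    amp_unit(profiles$cyt_c_red, nf_c, 1127), amp_unit(profiles$cyt_b_red, nf_b, 1127)
  ), nrow = 2, byrow = TRUE)
  sum_profile <- function(pf, nf) {
    s <- 0
    for (i in seq_len(nrow(pf))) {
      s <- s + sum(lorentzian(grid, pf$center[i], pf$fwhm[i], pf$rel_amp[i] / nf))
    }
    s
  }
  S_c <- sum_profile(profiles$cyt_c_red, nf_c)
  S_b <- sum_profile(profiles$cyt_b_red, nf_b)
  base <- synth_heart_spectrum(control, grid, seed = 1L)$truth
  isum_ctrl <- base$i_sum
  noncyt <- isum_ctrl - control$cyt_scale * (control$r_c * S_c + control$r_b * S_b)
  a750_ctrl <- control$cyt_scale * (control$r_c * u[1, 1] + control$r_b * u[1, 2])
  a1127_ctrl <- control$cyt_scale * (control$r_c * u[2, 1] + control$r_b * u[2, 2])

  g <- 1
  r <- c(control$r_c, control$r_b)
  for (iter in 1:50) {
    rhs <- c(target_750_pct / 100 * a750_ctrl,
             target_1127_pct / 100 * a1127_ctrl) * g / control$cyt_scale
    r_new <- solve(u, rhs)
    isum_f <- noncyt + control$cyt_scale * (r_new[1] * S_c + r_new[2] * S_b)
    g_new <- isum_f / isum_ctrl
    if (max(abs(r_new - r)) < 1e-12 && abs(g_new - g) < 1e-12) {
      r <- r_new; g <- g_new
      break
    }
    r <- r_new; g <- g_new
  }
  if (any(r <= 0) || any(r > 1)) {
    stop_ramanredox("FCCP targets give reduced fractions outside (0, 1]",
                    "ramanredox_validation_error")
  }
  physiological_state(
    f_dmb = control$f_dmb, r_c = r[1], r_b = r[2],
    mb_scale = control$mb_scale, cyt_scale = control$cyt_scale,
    q_true = control$q_true, baseline_amp = control$baseline_amp,
    noise_sd = control$noise_sd, amide_amp = control$amide_amp
  )
}

#' Named condition states of the study presets
#'
#' Ground-truth compositions for the eight experimental conditions the
#' simulator emulates. Control hearts are nearly fully oxygenated
#' (f_dmb = 0.05) with partially reduced cytochrome pools (r_c = r_b = 0.4).
#' The FCCP states keep myoglobin oxygenation fixed and lower the reduced
#' fractions so the sum-normalized 750/1127 cm^-1 intensities fall to the
#' tabulated 56.7%/42.3% (5 min) and 61.5%/37.3% (10 min) of control.
#' Stop-flow ischemia raises deoxygenation to 0.5 at 30 min and doubles the
#' reduced c-type fraction with the b-type pool unchanged; reperfusion
#' returns to the control state. Dithionite (SDT) fully reduces and fully
#' deoxygenates.
#'
#' @param control Baseline [physiological_state()] the presets derive from.
#' @return Named list of `physiological_state` objects: `control`,
#'   `fccp_5min`, `fccp_10min`, `ischemia_15`, `ischemia_30`,
#'   `reperfusion_5`, `reperfusion_30`, `sdt`.
#' @export
preset_states <- function(control = physiological_state()) {
  mod <- function(...) {
    args <- utils::modifyList(unclass(control), list(...))
    do.call(physiological_state, args)
  }
  list(
    control = control,
    fccp_5min = solve_fccp_state(56.7, 42.3, control),
    fccp_10min = solve_fccp_state(61.5, 37.3, control),
    ischemia_15 = mod(f_dmb = 0.25, r_c = min(1, 1.5 * control$r_c)),
    ischemia_30 = mod(f_dmb = 0.5, r_c = min(1, 2 * control$r_c)),
    reperfusion_5 = control,
    reperfusion_30 = control,
    sdt = mod(f_dmb = 1, r_c = 1, r_b = 1)
  )
}

#' Scenario presets for the emulated experiments
#'
#' Ready-made time courses with n = 3 replicates per timepoint: `control`
#' (a single control condition), `fccp` (control, 5 and 10 min of FCCP),
#' `ischemia` (control, 15 and 30 min stop-flow ischemia, 5 and 30 min
#' reperfusion) and `sdt` (control and full dithionite reduction).
#'
#' @param n_replicates Replicates per timepoint (default 3, as in the
#'   emulated experiments).
#' @param control Baseline [physiological_state()].
#' @return Named list of [scenario()] objects.
#' @export
scenario_presets <- function(n_replicates = 3L, control = physiological_state()) {
  st <- preset_states(control)
  tp <- function(label) list(label = label, state = st[[label]],
                             n_replicates = as.integer(n_replicates))
  list(
    control = scenario("control", list(tp("control"))),
    fccp = scenario("fccp", lapply(c("control", "fccp_5min", "fccp_10min"), tp)),
    ischemia = scenario("ischemia", lapply(
      c("control", "ischemia_15", "ischemia_30", "reperfusion_5",
        "reperfusion_30"), tp)),
    sdt = scenario("sdt", lapply(c("control", "sdt"), tp))
  )
}

#' Simulate a full scenario dataset
#'
#' Generates `n_replicates` spectra per timepoint with per-replicate seeds
#' derived deterministically from the master seed. Optionally writes the
#' dataset to disk as two-column spectrum files plus `manifest.csv`
#' (filename, condition, replicate, seed) and `ground_truth.csv`.
#'
#' @param scn A [scenario()].
#' @param grid Shift grid (cm^-1).
#' @param seed Master seed.
#' @param dir Output directory (created if missing); `NULL` keeps the
#'   dataset in memory only.
#' @return A list with `spectra` (named list of [raman_spectrum()]),
#'   `manifest` (data.frame) and `ground_truth` (data.frame with the state
#'   fields and true nu4/marker amplitudes per spectrum).
#' @export
synth_scenario <- function(scn, grid = default_grid(), seed = 1L, dir = NULL) {
  stopifnot(inherits(scn, "raman_scenario"))
  n_total <- sum(vapply(scn$timepoints, function(tp) tp$n_replicates, numeric(1)))
  seeds <- derive_seeds(seed, n_total)
  spectra <- list()
  manifest <- data.frame()
  truth <- data.frame()
  k <- 0L
  for (tp in scn$timepoints) {
    for (rep_i in seq_len(tp$n_replicates)) {
      k <- k + 1L
      sim <- synth_heart_spectrum(tp$state, grid, seeds[k])
      fname <- sprintf("%s_%s_rep%d.txt", scn$name, tp$label, rep_i)
      sim$spectrum$meta$condition <- tp$label
      sim$spectrum$meta$replicate <- rep_i
      spectra[[fname]] <- sim$spectrum
      manifest <- rbind(manifest, data.frame(
        filename = fname, condition = tp$label, replicate = rep_i,
        seed = seeds[k]
      ))
      ta <- sim$truth$band_amplitudes
      truth <- rbind(truth, data.frame(
        filename = fname, condition = tp$label, replicate = rep_i,
        f_dmb = tp$state$f_dmb, r_c = tp$state$r_c, r_b = tp$state$r_b,
        q_true = tp$state$q_true,
        amp_604 = unname(ta["604"]), amp_750 = unname(ta["750"]),
        amp_1127 = unname(ta["1127"]), amp_1337 = unname(ta["1337"]),
        amp_1358 = unname(ta["1358"]), amp_1377 = unname(ta["1377"]),
        i_sum = sim$truth$i_sum
      ))
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (fname in names(spectra)) {
      write_spectrum(spectra[[fname]], file.path(dir, fname), "two_column")
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(spectra = spectra, manifest = manifest, ground_truth = truth)
}
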
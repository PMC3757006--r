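local_maxima_at <- function(sp, centers, tol = 1) {
  y <- sp$intensities
  peaks <- sp$shifts[which(diff(sign(diff(y))) == -2) + 1]
  all(vapply(centers, function(cc) any(abs(peaks - cc) <= tol), logical(1)))
}

test_that("pure-component spectra peak at the assigned positions", {
  grid <- default_grid()
  pf <- component_profiles()
  expect_true(local_maxima_at(component_spectrum(pf$oMb, grid),
                              c(1377, 1587, 1640)))
  expect_true(local_maxima_at(component_spectrum(pf$dMb, grid),
                              c(1358, 1556, 1606)))
  expect_true(local_maxima_at(component_spectrum(pf$cyt_c_red, grid),
                              c(604, 750, 1310, 1582)))
  expect_equal(max(component_spectrum(pf$oMb, grid)$intensities), 1)
  # an empty profile gives an all-zero spectrum
  expect_equal(max(abs(component_spectrum(pf$cyt_ox, grid)$intensities)), 0)
})

test_that("the generator is deterministic in (state, seed)", {
  st <- physiological_state()
  a <- synth_heart_spectrum(st, seed = 7)
  b <- synth_heart_spectrum(st, seed = 7)
  expect_identical(a$spectrum$intensities, b$spectrum$intensities)
  c <- synth_heart_spectrum(st, seed = 8)
  expect_false(identical(a$spectrum$intensities, c$spectrum$intensities))
})

test_that("the mixture is linear in the abundance scalars", {
  grid <- default_grid()
  s1 <- noise_free_state(baseline_amp = 0)
  s2 <- noise_free_state(baseline_amp = 0, mb_scale = 2)
  a1 <- synth_heart_spectrum(s1, grid, 1)
  a2 <- synth_heart_spectrum(s2, grid, 1)
  expect_equal(a2$truth$band_amplitudes[c("1377", "1587", "1640")],
               2 * a1$truth$band_amplitudes[c("1377", "1587", "1640")])
  # and degenerate mixtures collapse to a single component
  pure <- noise_free_state(baseline_amp = 0, f_dmb = 0, r_c = 1e-12,
                           r_b = 1e-12, amide_amp = 0)
  pure$r_c <- 0; pure$r_b <- 0  # exact zeros
  sp <- synth_heart_spectrum(do.call(physiological_state, unclass(pure)),
                             grid, 1)$spectrum
  comp <- component_spectrum(component_profiles()$oMb, grid)
  ratio <- sp$intensities[comp$intensities > 1e-3] /
    comp$intensities[comp$intensities > 1e-3]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("dithionite reduction shows the expected marker changes", {
  grid <- default_grid()
  sdt <- synth_heart_spectrum(noise_free_state(f_dmb = 1, r_c = 1, r_b = 1),
                              grid, 1)
  ctl <- synth_heart_spectrum(noise_free_state(), grid, 2)
  a_sdt <- quantify_bands(corr_default(sdt$spectrum))
  a_ctl <- quantify_bands(corr_default(ctl$spectrum))
  # the 604 cm^-1 c-type marker appears and the oMb nu4 band vanishes
  expect_gt(a_sdt[["nu7_cytc_604"]], 0.02)
  expect_lt(a_sdt[["nu4_oMb_1377"]], 0.01)
  # full reduction increases the 750 and 1127 cm^-1 cytochrome bands
  expect_gt(a_sdt[["cyt_750"]], a_ctl[["cyt_750"]])
  expect_gt(a_sdt[["cyt_1127"]], a_ctl[["cyt_1127"]])
})

test_that("presets encode the experimental conditions", {
  st <- preset_states()
  expect_equal(st$control$f_dmb, 0.05)
  expect_equal(st$control$r_c, 0.4)
  expect_equal(st$ischemia_30$f_dmb, 0.5)
  expect_equal(st$ischemia_30$r_c, 2 * st$control$r_c)
  expect_equal(st$ischemia_30$r_b, st$control$r_b)
  expect_identical(st$reperfusion_5, st$control)
  expect_identical(st$reperfusion_30, st$control)
  expect_equal(st$sdt$f_dmb, 1)
  expect_equal(st$sdt$r_c, 1)
  # FCCP leaves myoglobin oxygenation untouched and lowers both pools
  expect_equal(st$fccp_5min$f_dmb, st$control$f_dmb)
  expect_lt(st$fccp_5min$r_c, st$control$r_c)
  expect_lt(st$fccp_5min$r_b, st$control$r_b)
  sc <- scenario_presets()
  expect_named(sc, c("control", "fccp", "ischemia", "sdt"))
  expect_length(sc$ischemia$timepoints, 5)
  expect_true(all(vapply(sc$ischemia$timepoints,
                         function(tp) tp$n_replicates == 3L, logical(1))))
})

test_that("scenario datasets have the right shape, seeds and files", {
  sc <- scenario_presets()
  d <- withr::local_tempdir()
  ds <- synth_scenario(sc$ischemia, seed = 5, dir = d)
  expect_equal(nrow(ds$manifest), 15)  # 5 timepoints x 3 replicates
  expect_length(ds$spectra, 15)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  expect_true(all(file.exists(file.path(d, ds$manifest$filename))))
  # replicates share ground truth but not noise
  ctrl <- ds$spectra[ds$manifest$condition == "control"]
  expect_false(identical(ctrl[[1]]$intensities, ctrl[[2]]$intensities))
  expect_equal(ds$ground_truth$f_dmb[ds$manifest$condition == "control"],
               rep(0.05, 3))
  # the same master seed reproduces the dataset exactly
  ds2 <- synth_scenario(sc$ischemia, seed = 5)
  expect_identical(ds$spectra[[1]]$intensities, ds2$spectra[[1]]$intensities)
  expect_identical(ds$manifest$seed, ds2$manifest$seed)
  # written spectra read back identically
  back <- read_spectrum(file.path(d, ds$manifest$filename[1]), "two_column")
  expect_equal(back$intensities, ds$spectra[[1]]$intensities, tolerance = 1e-9)
})

test_that("the analysis recovers the generator's ground truth without noise", {
  grid <- default_grid()
  sim <- synth_heart_spectrum(noise_free_state(), grid, 1)
  corrected <- corr_default(sim$spectrum)
  amps <- quantify_bands(corrected)
  truth <- sim$truth$band_amplitudes
  # major bands (>= 10% of the strongest) recovered within 2%
  major <- names(truth)[truth >= 0.1 * max(truth)]
  lib <- default_band_library()
  for (cc in major) {
    est <- amps[[which(abs(lib$center - as.numeric(cc)) < 0.5)]]
    expect_lt(abs(est - truth[[cc]]) / truth[[cc]], 0.02)
  }
  # the deoxygenation estimate lands within 0.01 of the true fraction
  idx <- spectrum_indices(corrected)
  expect_lt(abs(idx$f_dmb - 0.05), 0.01)
})

test_that("state validation rejects out-of-range compositions", {
  expect_error(physiological_state(f_dmb = 1.2),
               class = "ramanredox_validation_error")
  expect_error(physiological_state(r_c = -0.1),
               class = "ramanredox_validation_error")
  expect_error(physiological_state(cyt_scale = 0),
               class = "ramanredox_validation_error")
  expect_error(physiological_state(noise_sd = -1),
               class = "ramanredox_validation_error")
  expect_error(scenario("x", list()), class = "ramanredox_validation_error")
})
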
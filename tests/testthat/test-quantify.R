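test_that("band amplitude recovers an isolated noise-free Lorentzian", {
  grid <- seq(520, 1750, by = 1)
  sp <- lorentz_spectrum(grid, 1127, 100)
  expect_equal(band_amplitude(sp, 1127, mode = "height"), 100, tolerance = 1e-3)
  expect_equal(band_amplitude(sp, 1127, mode = "fit"), 100, tolerance = 1e-6)
  zero <- raman_spectrum(grid, rep(0, length(grid)))
  expect_equal(band_amplitude(zero, 1127, mode = "height"), 0)
  expect_equal(band_amplitude(zero, 1127, mode = "fit"), 0)
  short <- raman_spectrum(seq(600, 700, 1), rep(1, 101))
  expect_error(band_amplitude(short, 1127), class = "ramanredox_range_error")
})

test_that("amplitude and summed intensity are homogeneous of degree one", {
  grid <- seq(520, 1750, by = 1)
  sp <- lorentz_spectrum(grid, c(750, 1127, 1377), c(2, 5, 1))
  for (c in c(0.1, 3, 250)) {
    scaled <- raman_spectrum(grid, sp$intensities * c)
    expect_equal(band_amplitude(scaled, 750, mode = "height"),
                 c * band_amplitude(sp, 750, mode = "height"))
    expect_equal(band_amplitude(scaled, 1127, mode = "fit"),
                 c * band_amplitude(sp, 1127, mode = "fit"), tolerance = 1e-8)
    expect_equal(total_intensity(scaled), c * total_intensity(sp))
  }
})

test_that("fit mode resolves the overlapping 1582/1587 pair that height conflates", {
  grid <- seq(1500, 1750, by = 1)
  truth <- c(0.6, 1.0)
  sp <- lorentz_spectrum(grid, c(1582, 1587), truth)
  a82 <- band_amplitude(sp, 1582, mode = "fit")
  a87 <- band_amplitude(sp, 1587, mode = "fit")
  expect_lt(abs(a82 - truth[1]) / truth[1], 0.10)
  expect_lt(abs(a87 - truth[2]) / truth[2], 0.10)
  # height mode sees the summed profile: both windows report ~the joint max
  h82 <- band_amplitude(sp, 1582, mode = "height")
  expect_gt(h82, 1.2)
})

test_that("height of a noisy isolated band is at least the fitted amplitude", {
  grid <- seq(650, 850, by = 1)
  for (s in 1:5) {
    noise <- withr::with_seed(s, stats::runif(length(grid), 0, 0.3))
    sp <- raman_spectrum(grid, lorentzian(grid, 750, 14, 10) + noise)
    expect_gte(band_amplitude(sp, 750, mode = "height"),
               band_amplitude(sp, 750, mode = "fit"))
  }
})

test_that("regional decomposition recovers known mixtures", {
  grid <- seq(1500, 1750, by = 1)
  lib <- default_band_library()
  # single band present: exact recovery, others at zero
  one <- lorentz_spectrum(grid, 1606, 50)
  dec <- decompose_region(one, lib, c(1520, 1700))
  expect_equal(unname(dec$amplitudes["dMb_1606"]), 50, tolerance = 1e-6)
  expect_lt(max(dec$amplitudes[names(dec$amplitudes) != "dMb_1606"]), 1e-6)
  expect_lt(dec$residual_norm, 1e-6)
  # all-zero spectrum: all-zero amplitudes
  zero <- raman_spectrum(grid, rep(0, length(grid)))
  expect_equal(max(decompose_region(zero, lib, c(1520, 1700))$amplitudes), 0)
  # full five-band mixture, no noise: each within 5%
  centers <- c(1556, 1582, 1587, 1606, 1640)
  truth <- c(0.8, 0.5, 1.2, 0.4, 0.9)
  mix <- lorentz_spectrum(grid, centers, truth)
  dec2 <- decompose_region(mix, lib, c(1520, 1700))
  nm <- c("dMb_1556", "cyt_1582", "oMb_1587", "dMb_1606", "oMb_1640")
  expect_true(all(abs(dec2$amplitudes[nm] - truth) / truth < 0.05))
  expect_error(decompose_region(mix, lib, c(600, 700)),
               class = "ramanredox_range_error")
})

test_that("decomposition matches a brute-force amplitude search", {
  grid <- seq(1270, 1370, by = 1)
  lib <- default_band_library()
  centers <- c(1300, 1310, 1337)
  truth <- c(0.6, 0.4, 0.8)
  sp <- lorentz_spectrum(grid, centers, truth)
  X <- sapply(centers, function(cc) lorentzian(grid, cc, 14))
  sse <- function(a) sum((sp$intensities - X %*% a)^2)
  # two-stage exhaustive grid search over the amplitude cube
  cand <- as.matrix(expand.grid(seq(0, 1.2, 0.02), seq(0, 1.2, 0.02),
                                seq(0, 1.2, 0.02)))
  best <- cand[which.min(apply(cand, 1, sse)), ]
  fine <- as.matrix(expand.grid(seq(best[1] - 0.03, best[1] + 0.03, 0.002),
                                seq(best[2] - 0.03, best[2] + 0.03, 0.002),
                                seq(best[3] - 0.03, best[3] + 0.03, 0.002)))
  fine[fine < 0] <- 0
  brute <- fine[which.min(apply(fine, 1, sse)), ]
  dec <- decompose_region(sp, lib, c(1280, 1360), background = "none")
  nm <- c("cytb_1300", "cytc_1310", "cytb_1337")
  expect_true(all(abs(dec$amplitudes[nm] - brute) / brute < 0.02))
})

test_that("sub-resolution band spacing triggers the regularized path", {
  grid <- seq(700, 800, by = 2)
  lib <- band_library(
    raman_band("a", 750.0, species = "cyt_c_red"),
    raman_band("b", 750.9, species = "cyt_b_red")
  )
  sp <- lorentz_spectrum(grid, 750, 10)
  expect_warning(dec <- decompose_region(sp, lib, c(700, 800)),
                 "grid resolution")
  expect_true(dec$regularized)
  expect_equal(sum(dec$amplitudes), 10, tolerance = 0.1)
})

test_that("summed intensity behaves like a closed-interval sum", {
  grid <- seq(1000, 1099, by = 1)
  sp <- raman_spectrum(grid, rep(2, 100))
  expect_equal(total_intensity(sp, c(1000, 1099)), 200)
  expect_error(total_intensity(sp, c(1500, 1600)),
               class = "ramanredox_range_error")
  # fine-grid Lorentzian sum approximates the analytic integral
  g2 <- seq(520, 1750, by = 0.5)
  sp2 <- lorentz_spectrum(g2, 1127, 80)
  gam <- 7
  analytic <- 80 * gam * (atan((1750 - 1127) / gam) - atan((520 - 1127) / gam)) / 0.5
  expect_lt(abs(total_intensity(sp2) - analytic) / analytic, 0.01)
})

test_that("band library ships the heart assignment table", {
  lib <- default_band_library()
  expect_equal(nrow(lib), 14)
  expect_setequal(lib$center,
                  c(604, 750, 1127, 1300, 1310, 1337, 1358, 1377, 1556, 1582,
                    1587, 1606, 1640, 1658))
  expect_setequal(lib$center[lib$unique], c(604, 1337, 1358, 1377))
  # tissue-context downshift of the purified 1313 band
  expect_true(1313 %in% default_band_library("purified")$center)
  # CSV round trip, and the shipped library file matches the in-code default
  f <- withr::local_tempfile(fileext = ".csv")
  write_band_library(lib, f)
  expect_equal(read_band_library(f)$center, lib$center)
  shipped <- system.file("extdata", "heart_band_library.csv",
                         package = "ramanredox")
  expect_equal(as.data.frame(read_band_library(shipped)), as.data.frame(lib))
  expect_error(raman_band("x", 750, species = "cyt_c_red", unique = TRUE),
               class = "ramanredox_validation_error")
})
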
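test_that("Savitzky-Golay smoother reproduces polynomials exactly", {
  # a polynomial of degree <= polyorder is a fixed point of the filter
  x <- seq_len(101)
  y <- 2 + 0.3 * x + 0.01 * x^2
  expect_equal(savitzky_golay(y, 11, 2)[6:96], y[6:96], tolerance = 1e-8)
  expect_error(savitzky_golay(y, 10, 2), "odd")
  expect_error(savitzky_golay(y, 3, 4), "odd|polyorder")
})

test_that("baseline of a flat or peakless spectrum is the spectrum itself", {
  flat <- spectrum(seq(2600, 3600, 10), rep(3, 101))
  b <- baseline_correct(flat, window = 21)
  expect_equal(b$baseline$intensity, flat$intensity, tolerance = 1e-9)
  expect_equal(b$corrected$intensity, rep(0, 101), tolerance = 1e-9)
  ramp <- spectrum(seq(2600, 3600, 10), seq(1, 5, length.out = 101))
  br <- baseline_correct(ramp, window = 21)
  expect_lt(max(abs(br$corrected$intensity)), 0.01 * diff(range(ramp$intensity)))
})

test_that("baseline is a lower envelope and correction is near-idempotent", {
  # band widths well below the 101-point baseline window: the envelope
  # scheme treats anything wider than ~half the window as background
  s <- generate_synthetic_spectrum(
    bands = list(c(2890, 15, 1), c(3100, 12, 0.6)),
    baseline_poly = c(2, 1.5, -0.8), noise_sigma = 0, seed = 2)
  b <- baseline_correct(s)
  expect_true(all(b$baseline$intensity <= s$intensity + 1e-9))
  again <- baseline_correct(b$corrected)
  expect_lt(max(abs(again$corrected$intensity - b$corrected$intensity)),
            0.01 * max(b$corrected$intensity))
})

test_that("band parameters are recovered from a corrupted spectrum", {
  truth <- list(c(2887, 6, 1.0), c(2933, 6, 0.7), c(3100, 12, 0.5))
  s <- generate_synthetic_spectrum(bands = truth,
                                   baseline_poly = c(1, 2),
                                   noise_sigma = 0.005, seed = 4)
  corr <- baseline_correct(s)$corrected
  for (b in truth) {
    sel <- abs(corr$wavenumbers - b[1]) <= 3 * b[2]
    pk <- corr$wavenumbers[sel][which.max(corr$intensity[sel])]
    expect_lt(abs(pk - b[1]), 2)                       # +-2 1/cm
    expect_equal(max(corr$intensity[sel]), b[3], tolerance = 0.1)
  }
})

test_that("peak ratios behave: identity, closed form, scale invariance", {
  s <- generate_synthetic_spectrum(bands = list(c(2890, 10, 2), c(3100, 10, 1)),
                                   noise_sigma = 0, seed = 1)
  expect_equal(peak_ratio(s, c(2870, 2910), c(2870, 2910)), 1)
  expect_equal(peak_ratio(s, c(2870, 2910), c(3080, 3120)), 2,
               tolerance = 1e-6)
  s2 <- spectrum(s$wavenumbers, 7.3 * s$intensity)
  expect_equal(peak_ratio(s2, c(2870, 2910), c(3080, 3120)),
               peak_ratio(s, c(2870, 2910), c(3080, 3120)))
  expect_error(peak_ratio(s, c(100, 200), c(3080, 3120)), "no samples")
  # integral mode keeps the amplitude ordering for equal-width bands
  expect_equal(peak_ratio(s, c(2870, 2910), c(3080, 3120),
                          mode = "integral"), 2, tolerance = 0.05)
})

test_that("band assignment places peaks into the printed intervals", {
  s <- generate_synthetic_spectrum(bands = list(c(2885, 4, 1)),
                                   noise_sigma = 0, seed = 1)
  a <- assign_bands(s, noise_floor = 0.1)
  row <- a[a$mode == "CH2 asymmetric stretching", ]
  expect_true(row$present)
  expect_equal(row$peak_position, 2885, tolerance = 1)
  # empty spectrum: nothing present
  empty <- generate_synthetic_spectrum(list(), noise_sigma = 0)
  expect_true(all(!assign_bands(empty, noise_floor = 0.01)$present))
  # a peak between the table rows is matched by no narrow band
  s2 <- generate_synthetic_spectrum(bands = list(c(2915, 3, 1)),
                                    noise_sigma = 0, seed = 1)
  a2 <- assign_bands(s2, noise_floor = 0.5)
  expect_false(a2$present[a2$mode == "CH2 asymmetric stretching"])
  expect_false(a2$present[a2$mode == "CH3 stretching"])
})

test_that("raman_shift arithmetic and the instrument presets", {
  expect_equal(raman_shift(532, 532), 0)
  expect_equal(raman_shift(532, 631.6), 1e7 * (1 / 532 - 1 / 631.6))
  expect_equal(raman_shift(532, 631.6), 2964, tolerance = 0.5)
  expect_equal(raman_shift(660, 815), 2881.6, tolerance = 0.5)
  # antisymmetry under swapping, anti-Stokes flagged
  expect_warning(as_shift <- raman_shift(631.6, 532), "anti-Stokes")
  expect_equal(as_shift, -raman_shift(532, 631.6))
  expect_error(raman_shift(-1, 500), "positive")
  # both Raman presets land in the C-H stretching region
  pre <- modality_presets()
  raman <- pre[pre$modality == "raman", ]
  shifts <- mapply(raman_shift, raman$excitation_nm, raman$detected_nm)
  expect_true(all(shifts > 2850 & shifts < 3400))
})

test_that("spectrum CSV round trip", {
  s <- generate_synthetic_spectrum(bands = list(c(3000, 20, 1)),
                                   noise_sigma = 0.01, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, p)
  r <- read_spectrum(p)
  expect_equal(r$wavenumbers, s$wavenumbers)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-12)
})
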
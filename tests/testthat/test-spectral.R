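test_that("resampling follows the intersection-and-finer-step rule", {
  a <- gaussian_spectrum(600, 1, range = c(400, 800), step = 1)
  b <- gaussian_spectrum(600, 1, range = c(450, 900), step = 2)
  rs <- resample_to_common_grid(a, b)
  expect_equal(range(rs$a$wavelength_nm), c(450, 800))
  expect_equal(unique(diff(rs$a$wavelength_nm)), 1)
  expect_identical(rs$a$wavelength_nm, rs$b$wavelength_nm)

  # identical grids pass through untouched
  rs2 <- resample_to_common_grid(a, a)
  expect_identical(rs2$a$intensity, a$intensity)

  # linear interpolation reproduces linear spectra exactly
  wl <- seq(400, 800, by = 1)
  lin <- spectrum(wl, 0.2 + 0.001 * wl)
  rs3 <- resample_to_common_grid(lin, b)
  expect_equal(rs3$a$intensity, 0.2 + 0.001 * rs3$a$wavelength_nm,
               tolerance = 1e-12)

  disjoint <- gaussian_spectrum(950, 1, range = c(900.5, 1000))
  expect_error(resample_to_common_grid(a, disjoint), "disjoint")
})

test_that("difference spectra are antisymmetric and null on self", {
  s <- gaussian_spectrum(c(465, 612), c(0.4, 1))
  expect_true(all(difference_spectrum(s, s)$delta == 0))

  t <- gaussian_spectrum(c(465, 711), c(0.4, 1))
  ab <- difference_spectrum(s, t)
  ba <- difference_spectrum(t, s)
  expect_identical(ab$delta, -ba$delta)

  absb <- gaussian_spectrum(410, 1, kind = "absorbance")
  expect_error(difference_spectrum(s, absb), "different kinds")
})

test_that("a subtrahend-side negative band appears as one dominant dip", {
  base <- gaussian_spectrum(c(465, 612), c(0.4, 1), widths = c(18, 50))
  # subtracting a spectrum that lacks intensity at 536 nm leaves a dip there
  with_dip <- gaussian_spectrum(c(465, 612, 536), c(0.4, 1, 0.3),
                                widths = c(18, 50, 8), sign = c(1, 1, -1))
  ds <- difference_spectrum(with_dip, base)
  feats <- detect_quantized_features(ds, min_prominence = 0.05)
  expect_gte(nrow(feats), 1L)
  expect_lte(abs(feats$wavelength_nm[1] - 536), 1)
})

test_that("feature detection respects polarity, threshold and empty input", {
  s <- gaussian_spectrum(600, 1)
  zero <- difference_spectrum(s, s)
  expect_equal(nrow(detect_quantized_features(zero, 0.01)), 0L)

  two <- gaussian_spectrum(c(500, 700), c(1.0, 0.1), widths = 15,
                           sign = c(-1, -1), baseline = 2)
  flatref <- gaussian_spectrum(numeric(0), numeric(0), baseline = 2)
  ds <- difference_spectrum(two, flatref, normalization = "none")
  kept <- detect_quantized_features(ds, min_prominence = 0.5)
  expect_equal(nrow(kept), 1L)
  expect_lte(abs(kept$wavelength_nm - 500), 1)
  # both found at a permissive threshold, sorted by prominence
  all_f <- detect_quantized_features(ds, min_prominence = 0.05)
  expect_equal(nrow(all_f), 2L)
  expect_true(all(diff(all_f$prominence) <= 0))
})

test_that("windowed peak localization is accurate, tie-broken and baseline-proof", {
  s <- gaussian_spectrum(612, 1, widths = 40)
  expect_lte(abs(peak_max(s, c(550, 800)) - 612), 1)

  two <- gaussian_spectrum(c(568, 711), c(0.8, 1), widths = 30)
  expect_lte(abs(peak_max(two, c(650, 800)) - 711), 1)
  expect_lte(abs(peak_max(two, c(500, 620)) - 568), 1)

  flat <- gaussian_spectrum(numeric(0), numeric(0), baseline = 0.2)
  expect_warning(w <- peak_max(flat, c(500, 700)), "No distinct peak")
  expect_equal(w, 600)

  shifted <- spectrum(s$wavelength_nm, s$intensity + 5)
  expect_identical(peak_max(shifted, c(550, 800)), peak_max(s, c(550, 800)))

  expect_error(peak_max(s, c(1000, 1100)), "fewer than 5")
})

test_that("Soret shifts call the redox state with a symmetric threshold", {
  pre <- gaussian_spectrum(414, 1, widths = 12, range = c(350, 500),
                           kind = "absorbance")
  same <- soret_shift_call(pre, pre)
  expect_equal(same$shift_nm, 0)
  expect_identical(same$call, "unchanged")

  post <- gaussian_spectrum(409, 1, widths = 12, range = c(350, 500),
                            kind = "absorbance")
  blue <- soret_shift_call(pre, post)
  expect_equal(blue$shift_nm, -5)
  expect_identical(blue$call, "oxidized")

  barely <- gaussian_spectrum(415, 1, widths = 12, range = c(350, 500),
                              kind = "absorbance")
  expect_identical(soret_shift_call(pre, barely)$call, "unchanged")
  red <- gaussian_spectrum(418, 1, widths = 12, range = c(350, 500),
                           kind = "absorbance")
  expect_identical(soret_shift_call(pre, red)$call, "reduced")

  narrow <- gaussian_spectrum(414, 1, range = c(400, 500),
                              kind = "absorbance")
  expect_error(soret_shift_call(narrow, narrow), "Soret window")
  expect_error(soret_shift_call(gaussian_spectrum(414, 1, range = c(350, 500)),
                                post),
               "absorbance")
})

test_that("max normalization makes differences scale-invariant", {
  a <- gaussian_spectrum(c(465, 612), c(0.4, 1))
  b <- gaussian_spectrum(c(465, 711), c(0.4, 1))
  ref <- difference_spectrum(a, b, normalization = "max")
  for (k in c(0.01, 3, 250)) {
    scaled <- spectrum(a$wavelength_nm, k * a$intensity)
    ds <- difference_spectrum(scaled, b, normalization = "max")
    expect_equal(ds$delta, ref$delta, tolerance = 1e-12)
  }
})
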
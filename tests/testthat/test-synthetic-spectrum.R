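test_that("single-band spectra peak at the requested centre", {
  p <- spectrum_sim_params(
    bands = data.frame(center_nm = 612, width_nm = 40, amplitude = 1,
                       sign = 1),
    baseline = 0, noise_sd = 0)
  s <- simulate_spectrum(p)
  expect_lte(abs(s$wavelength_nm[which.max(s$intensity)] - 612), 1)
})

test_that("band-free spectra are the constant baseline", {
  p <- spectrum_sim_params(bands = data.frame(), baseline = 0.2,
                           noise_sd = 0)
  s <- simulate_spectrum(p)
  expect_true(all(s$intensity == 0.2))
})

test_that("two-band spectra round-trip through windowed peak finding", {
  p <- spectrum_sim_params(
    bands = data.frame(center_nm = c(568, 711), width_nm = c(30, 40),
                       amplitude = c(0.8, 1), sign = c(1, 1)),
    baseline = 0.05, noise_sd = 0)
  s <- simulate_spectrum(p)
  expect_lte(abs(peak_max(s, c(500, 640)) - 568), 1)
  expect_lte(abs(peak_max(s, c(650, 800)) - 711), 1)
})

test_that("out-of-range bands warn but are still rendered", {
  p <- spectrum_sim_params(
    bands = data.frame(center_nm = 380, width_nm = 40, amplitude = 1,
                       sign = 1),
    wavelength_range = c(400, 900), baseline = 0, noise_sd = 0)
  expect_warning(s <- simulate_spectrum(p), "truncated")
  expect_gt(s$intensity[1], s$intensity[100])  # in-range tail present
})

test_that("spectrum noise is seed-deterministic", {
  p <- spectrum_sim_params(noise_sd = 0.01, seed = 9)
  expect_identical(simulate_spectrum(p)$intensity,
                   simulate_spectrum(p)$intensity)
  expect_error(simulate_spectrum(spectrum_sim_params(noise_sd = 0.01)),
               "seed")
  expect_error(spectrum_sim_params(wavelength_range = c(900, 400)),
               "wavelength_range")
  expect_error(spectrum_sim_params(
    bands = data.frame(center_nm = 612, width_nm = -1, amplitude = 1,
                       sign = 1)), "width")
})
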
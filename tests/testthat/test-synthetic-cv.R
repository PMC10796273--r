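test_that("near-reversible simulation reproduces the Nernstian peak separation", {
  dEp <- peak_sep(1, 0.1)
  expect_gt(dEp, 0.056)
  expect_lt(dEp, 0.062)
})

test_that("quasi-reversible peak separation grows with scan rate", {
  # the bifunctionalized-particle rate regime
  slow <- peak_sep(3.75e-3, 0.05)
  fast <- peak_sep(3.75e-3, 0.5)
  expect_gt(fast, slow)
})

test_that("identical parameters and seed give bit-identical voltammograms", {
  p <- cv_sim_params(k0_true = 5e-3, scan_rate = 0.5,
                     noise_sd_current = 1e-7, seed = 3L)
  v1 <- simulate_voltammogram(p)
  v2 <- simulate_voltammogram(p)
  expect_identical(v1$current_A, v2$current_A)
  expect_identical(v1$potential_V, v2$potential_V)
  # different seed changes the noise
  p$seed <- 4L
  v3 <- simulate_voltammogram(p)
  expect_false(identical(v1$current_A, v3$current_A))
})

test_that("halving both grid steps moves extracted peaks by under 1 mV", {
  pk <- function(dE) {
    vg <- simulate_voltammogram(cv_sim_params(
      k0_true = 5e-3, scan_rate = 0.5, grid = list(dE = dE, lambda = 0.45)))
    detect_redox_peaks(vg)
  }
  coarse <- pk(1e-3)
  fine <- pk(5e-4)   # halves dt, hence dx, at fixed lambda
  expect_lt(abs(coarse$E_pa - fine$E_pa), 1e-3)
  expect_lt(abs(coarse$E_pc - fine$E_pc), 1e-3)
})

test_that("invalid grids and sweeps are rejected", {
  expect_error(
    simulate_voltammogram(cv_sim_params(k0_true = 1e-3,
                                        grid = list(lambda = 0.6))),
    class = "qbetr_discretization_error")
  expect_error(cv_sim_params(k0_true = 1e-3, E_start = 0.5, E_reverse = 0.5),
               "Degenerate sweep")
  expect_error(cv_sim_params(k0_true = -1), "k0_true")
  expect_error(cv_sim_params(k0_true = 1e-3, alpha_ct_true = 1.2),
               "alpha_ct_true")
})

test_that("scan-rate studies are ordered, validated and flag degenerate cases", {
  st <- sim_study(5e-3, rates = c(2, 0.1, 0.5))
  expect_s3_class(st, "scan_rate_study")
  expect_identical(st$scan_rate, c(0.1, 0.5, 2))
  expect_true(attr(st, "sufficient_for_regression"))

  single <- sim_study(5e-3, rates = 0.1)
  expect_false(attr(single, "sufficient_for_regression"))

  p <- cv_sim_params(k0_true = 5e-3)
  expect_error(simulate_scan_rate_study(p, numeric()), "non-empty")
  expect_error(simulate_scan_rate_study(p, c(0.1, 0.1)), "distinct")
})
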
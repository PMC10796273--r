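test_that("peak detection finds both peaks and rejects flat traces", {
  vg <- simulate_voltammogram(cv_sim_params(k0_true = 1, scan_rate = 0.1))
  pp <- detect_redox_peaks(vg)
  expect_gt(pp$delta_Ep, 0)
  expect_true(pp$E_pc < pp$E_formal & pp$E_formal < pp$E_pa)

  flat <- triangle_vgram(rep(0, 201))
  expect_error(detect_redox_peaks(flat), class = "qbetr_no_peak")
})

test_that("peak separation comparison across scan rates is resolved", {
  expect_gt(peak_sep(5e-3, 1), peak_sep(5e-3, 0.1))
})

test_that("transfer-coefficient regression reproduces hand-computed values", {
  # slope of -2.3RT/(nF) V per decade corresponds to alpha = 1
  pts <- data.frame(scan_rate = c(1, 10, 100),
                    delta_E = c(0, -0.05908, -0.11816))
  fit <- transfer_coefficient_fit(pts)
  expect_equal(fit$slope, -0.05908, tolerance = 1e-10)
  expect_equal(fit$alpha_ct, 1.0, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)

  # doubling the slope halves alpha
  pts2 <- data.frame(scan_rate = c(1, 10, 100),
                     delta_E = c(0, -0.11816, -0.23632))
  expect_equal(transfer_coefficient_fit(pts2)$alpha_ct, 0.5,
               tolerance = 1e-3)
})

test_that("transfer-coefficient regression flags sign and identifiability issues", {
  pts <- data.frame(scan_rate = c(1, 10, 100),
                    delta_E = c(0, 0.05908, 0.11816))  # anodic-signed slope
  expect_warning(fit <- transfer_coefficient_fit(pts), "unexpected sign")
  expect_equal(fit$alpha_ct, 1, tolerance = 1e-3)

  shallow <- data.frame(scan_rate = c(1, 10, 100),
                        delta_E = c(0, -0.005, -0.01))
  expect_warning(fit2 <- transfer_coefficient_fit(shallow), "clamped")
  expect_equal(fit2$alpha_ct, 1.5)

  expect_error(transfer_coefficient_fit(pts[1:2, ]), "At least 3")
})

test_that("psi working function matches hand evaluation and is monotone", {
  expect_equal(compute_psi(0.5, 1, 0), 0.8697, tolerance = 5e-4)
  expect_equal(compute_psi(0.5, 1, 0.1), 0.329, tolerance = 2e-3)
  # strictly decreasing in delta_Ep for any alpha
  for (a in c(0.3, 0.5, 0.9)) {
    psis <- compute_psi(a, 1, seq(0, 0.4, by = 0.05))
    expect_true(all(diff(psis) < 0))
    expect_true(all(psis > 0))
  }
  expect_error(compute_psi(0.5, 1, -0.01), "delta_Ep")
  # a millivolt-scale input would change psi by more than 10x, so values
  # above 1.5 V are rejected as probable unit errors
  expect_gt(compute_psi(0.5, 1, 0.3 * 1e-3) / compute_psi(0.5, 1, 0.3), 10)
  expect_error(compute_psi(0.5, 1, 100), "millivolt")
})

test_that("rate-constant conversion matches hand evaluation and scalings", {
  expect_equal(compute_k0(0.5, D_coeff = 1e-6, scan_rate = 0.1), 1.75e-3,
               tolerance = 2e-3)
  k <- compute_k0(0.4, D_coeff = 1e-6, scan_rate = 0.2)
  expect_equal(compute_k0(0.8, D_coeff = 1e-6, scan_rate = 0.2), 2 * k,
               tolerance = 1e-12)
  expect_equal(compute_k0(0.4, D_coeff = 1e-6, scan_rate = 0.8), 2 * k,
               tolerance = 1e-12)
  expect_error(compute_k0(0.5, scan_rate = 0.1),
               class = "qbetr_config_error")
})

test_that("study analysis recovers k0 in the working function's domain", {
  # 2e-3 cm/s at 0.1-2 V/s puts peak separations around 100-200 mV, where
  # the exponential working function tracks the true working curve
  st <- sim_study(2e-3)
  res <- analyze_study(st, D_coeff = 1e-6, alpha_ct = 0.5)
  expect_lt(abs(res$k0_mean - 2e-3) / 2e-3, 0.25)
  expect_true(all(res$per_rate$psi > 0))
  expect_gt(res$k0_mean, 0)

  gl <- glance(res)
  expect_equal(gl$n_rates, 5L)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("near-reversible studies are refused for rate extraction", {
  st <- sim_study(1, rates = c(0.1, 0.2, 0.5))  # all peaks ~58 mV apart
  expect_error(analyze_study(st, D_coeff = 1e-6, alpha_ct = 0.5),
               class = "qbetr_analysis_error")
})

test_that("small current noise perturbs k0 within its reported spread", {
  mean_k0 <- function(seed) {
    st <- sim_study(2e-3, rates = c(0.2, 0.5, 1, 2),
                    noise_sd_current = 5e-8, seed = seed)
    analyze_study(st, D_coeff = 1e-6, alpha_ct = 0.5)
  }
  r1 <- mean_k0(1L)
  r2 <- mean_k0(100L)
  expect_lt(abs(r1$k0_mean - r2$k0_mean), 3 * r1$k0_sd)
})
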
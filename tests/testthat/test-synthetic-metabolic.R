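test_that("noiseless generation matches the survival closed form", {
  p <- metabolic_sim_params(beta_true = 0.1, alpha_loc_true = 0,
                            noise_sd_activity = 0, times = 12)
  d <- simulate_metabolic_dataset(p)
  # alpha = 0 removes the length dependence: every well at exp(-1.2)
  expect_true(all(abs(d$activity_fraction - exp(-1.2)) < 1e-14))

  p0 <- metabolic_sim_params(noise_sd_activity = 0, times = 0)
  expect_true(all(simulate_metabolic_dataset(p0)$activity_fraction == 1))
})

test_that("noiseless rows invert exactly to the true condition rate", {
  p <- metabolic_sim_params(noise_sd_activity = 0, times = 12)
  d <- simulate_metabolic_dataset(p)
  r_true <- p$beta_true * exp(-p$alpha_loc_true * d$linker_length_nm)
  r_back <- charging_rate_from_activity(d$activity_fraction, d$time_h)
  expect_true(all(abs(r_back - r_true) / r_true < 1e-12))
})

test_that("per-cell mean activity stays within 3 standard errors of the model", {
  p <- metabolic_sim_params(seed = 7, replicates = 9,
                            noise_sd_activity = 0.05)
  d <- simulate_metabolic_dataset(p)
  by_cell <- dplyr::summarise(
    dplyr::group_by(d, .data$diameter_nm, .data$linker_kda,
                    .data$linker_length_nm),
    m = mean(.data$activity_fraction),
    se = stats::sd(.data$activity_fraction) / sqrt(dplyr::n()),
    .groups = "drop")
  expected <- exp(-p$beta_true * exp(-p$alpha_loc_true *
                                       by_cell$linker_length_nm) * 12)
  expect_true(all(abs(by_cell$m - expected) <= 3 * by_cell$se))
})

test_that("metabolic generation is seed-deterministic and clipped", {
  p <- metabolic_sim_params(seed = 5, noise_sd_activity = 0.4)
  d1 <- simulate_metabolic_dataset(p)
  d2 <- simulate_metabolic_dataset(p)
  expect_identical(d1$activity_fraction, d2$activity_fraction)
  expect_true(all(d1$activity_fraction > 0 & d1$activity_fraction <= 1.5))

  expect_error(simulate_metabolic_dataset(metabolic_sim_params()),
               "seed")
  expect_error(metabolic_sim_params(beta_true = -1), "beta_true")
  expect_error(metabolic_sim_params(replicates = 0), "replicates")
})

test_that("the generated grid covers the full design", {
  p <- metabolic_sim_params(noise_sd_activity = 0)
  d <- simulate_metabolic_dataset(p)
  expect_equal(nrow(d), 3 * 4 * 1 * 9)
  expect_setequal(unique(d$linker_kda), c(1, 2, 3.5, 5))
  expect_setequal(unique(d$diameter_nm), c(20, 50, 100))
  expect_identical(
    attr(d, "sim_params")$beta_true, p$beta_true)
})
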
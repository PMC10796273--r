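test_that("charging rate inverts the survival model", {
  expect_equal(charging_rate_from_activity(1, 12), 0)
  expect_equal(charging_rate_from_activity(exp(-1), 1), 1)
  expect_equal(charging_rate_from_activity(0.5, 12), log(2) / 12)
  expect_error(charging_rate_from_activity(0.5, 0), "time")
  expect_error(charging_rate_from_activity(0, 12), "activity")
  expect_error(charging_rate_from_activity(-0.1, 12), "activity")
  # activity above control gives a negative (allowed) rate
  expect_lt(charging_rate_from_activity(1.1, 12), 0)
})

test_that("activity prediction and rate extraction are mutual inverses", {
  expect_equal(predicted_activity(0, 37), 1)
  expect_equal(predicted_activity(log(2) / 12, 12), 0.5)
  for (r in c(0.01, 0.1, 1)) {
    expect_equal(charging_rate_from_activity(predicted_activity(r, 7.3), 7.3),
                 r, tolerance = 1e-12)
  }
})

test_that("survival evolution conserves totals and obeys the semigroup law", {
  s0 <- survival_state(1000)
  expect_identical(evolve_survival(s0, 0, 5)$alive, 1000)

  half <- evolve_survival(s0, log(2), 1)
  expect_equal(half$alive, 500)
  expect_equal(half$dead, 500)

  two_steps <- evolve_survival(evolve_survival(s0, 0.3, 1), 0.3, 1)
  one_step <- evolve_survival(s0, 0.3, 2)
  expect_equal(two_steps$alive, one_step$alive, tolerance = 1e-12)

  # arbitrary update sequence conserves the total exactly
  s <- survival_state(123.5, 7)
  for (dt in c(0.1, 3, 0.01, 12, 5)) {
    s <- evolve_survival(s, runif(1, 0, 0.5), dt)
    expect_identical(s$total, 130.5)
    expect_equal(s$alive + s$dead, s$total)
  }
  expect_error(evolve_survival(s0, 0.1, -1), "dt")
})

test_that("linker mass converts to length under the contour convention", {
  expect_equal(linker_length_from_mw(2), 15.89, tolerance = 1e-3)
  expect_equal(linker_length_from_mw(1), 7.94, tolerance = 1e-2)
  expect_equal(linker_length_from_mw(2, convention = "custom",
                                     nm_per_monomer = 0.28),
               12.71, tolerance = 1e-3)
  # linear in mass
  expect_equal(linker_length_from_mw(5), 5 * linker_length_from_mw(1))
  expect_error(linker_length_from_mw(0), "linker_mass")
})

test_that("charging rates aggregate per replicate, then average", {
  d <- tibble::tibble(
    cell_line = "GIN 31", diameter_nm = 100, linker_kda = 2,
    time_h = 12, activity_fraction = c(0.5, 0.5, 0.5), replicate = 1:3)
  agg <- aggregate_charging_rates(d)
  expect_equal(agg$r_d, log(2) / 12, tolerance = 1e-12)
  expect_equal(agg$se, 0)
  expect_equal(agg$n_replicates, 3L)

  # mean of per-replicate rates, not the rate of the mean activity
  d2 <- d
  d2$activity_fraction <- c(0.4, 0.5, 0.6)
  agg2 <- aggregate_charging_rates(d2)
  expect_equal(agg2$r_d, mean(-log(c(0.4, 0.5, 0.6)) / 12))
  expect_false(isTRUE(all.equal(agg2$r_d, -log(mean(c(0.4, 0.5, 0.6))) / 12)))

  # activity gain: tagged, negative mean rate, excluded from fitting
  d3 <- d[1:2, ]
  d3$activity_fraction <- c(1.1, 1.2)
  expect_warning(aggregate_charging_rates(d3), "non-positive")
  agg3 <- suppressWarnings(aggregate_charging_rates(d3))
  expect_true(agg3$activity_gain)
  expect_lt(agg3$r_d, 0)
  expect_false(agg3$usable)
})

test_that("noiseless barrier-decay fits are exact and both methods agree", {
  L <- c(8, 16, 28, 40)
  pts <- data.frame(linker_length_nm = L, r_d = 0.1 * exp(-0.1 * L))
  fit <- fit_barrier_decay(pts)
  expect_equal(fit$alpha_loc, 0.1, tolerance = 1e-6)
  expect_equal(fit$beta, 0.1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # log-linear initialization agrees to < 1% on clean data
  expect_lt(abs(fit$loglinear[["alpha_loc"]] - fit$alpha_loc) / 0.1, 0.01)
  expect_lt(abs(fit$loglinear[["beta"]] - fit$beta) / 0.1, 0.01)

  td <- tidy(fit)
  expect_identical(td$term, c("alpha_loc", "beta"))
})

test_that("flat rate data degrade to zero decay with a warning", {
  pts <- data.frame(linker_length_nm = c(8, 16, 28, 40), r_d = 0.05)
  expect_warning(fit <- fit_barrier_decay(pts), "degenerate")
  expect_equal(fit$alpha_loc, 0, tolerance = 1e-8)
  expect_equal(fit$beta, 0.05, tolerance = 1e-8)
})

test_that("degenerate barrier-fit inputs error cleanly", {
  expect_error(
    fit_barrier_decay(data.frame(linker_length_nm = c(8, 16), r_d = c(1, 2))),
    class = "qbetr_fit_error")
  expect_error(
    fit_barrier_decay(data.frame(linker_length_nm = rep(8, 4),
                                 r_d = c(1, 2, 3, 4))),
    class = "qbetr_fit_error")
  # non-positive rates are dropped before fitting
  expect_error(
    fit_barrier_decay(data.frame(linker_length_nm = c(8, 16, 28, 40),
                                 r_d = c(0.1, -0.1, 0, 0.05))),
    class = "qbetr_fit_error")
})

test_that("simulated-grid barrier recovery lands within two standard errors", {
  params <- metabolic_sim_params(seed = 11)
  d <- simulate_metabolic_dataset(params)
  agg <- aggregate_charging_rates(d)
  fit <- fit_barrier_decay(agg)
  expect_lt(abs(fit$alpha_loc - params$alpha_loc_true), 2 * fit$alpha_se)
  expect_lt(abs(fit$beta - params$beta_true), 2 * fit$beta_se)
})

test_that("hop-distance bound reproduces the worked feasibility example", {
  hop <- max_hop_distance(3.75e-3, 3e6)
  expect_equal(hop$d_max_nm, 1.25e-2, tolerance = 1e-12)
  expect_equal(hop$d_max_nm_1sf, 0.01)

  expect_equal(max_hop_distance(9.6e-3, 3e6)$d_max_nm, 3.2e-2,
               tolerance = 1e-12)
  # inverse proportionality in frequency
  expect_equal(max_hop_distance(3.75e-3, 6e6)$d_max_nm, 1.25e-2 / 2)
  # dimensional identity: nm result equals (cm/s) * 1e7 / Hz
  expect_equal(max_hop_distance(2e-3, 1e5)$d_max_nm, 2e-3 * 1e7 / 1e5)
})

test_that("classical feasibility verdicts respect the inclusive boundary", {
  expect_false(classical_feasibility(0.0125, 15.89)$classical_possible)
  expect_true(classical_feasibility(20, 15.89)$classical_possible)
  expect_true(classical_feasibility(15.89, 15.89)$classical_possible)
})
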
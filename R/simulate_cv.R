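#' Parameters for the cyclic-voltammetry simulator
#'
#' Ground-truth parameters of the one-electron quasi-reversible Butler-Volmer
#' couple with semi-infinite planar diffusion that the simulator solves by
#' explicit finite differences. Both redox forms share the diffusion
#' coefficient, so the total concentration profile stays uniform and only the
#' reduced-form profile is propagated.
#'
#' @param k0_true Standard heterogeneous rate constant, cm s^-1 (> 0).
#' @param alpha_ct_true Transfer coefficient, in (0, 1).
#' @param n_electrons Electrons transferred (positive integer).
#' @param D_coeff Diffusion coefficient, cm^2 s^-1 (> 0). The default 1e-6 is
#'   a typical literature magnitude for cytochrome c in aqueous buffer.
#' @param E_formal_true Formal potential of the couple, V.
#' @param E_start,E_reverse Start and switching potentials of the triangular
#'   sweep, V. Defaults follow the instrument window +1.2 V to -0.2 V.
#' @param scan_rate Sweep rate, V s^-1 (> 0).
#' @param temperature_K Temperature, kelvin.
#' @param electrode_area_cm2 Electrode area, cm^2 (sets the current scale
#'   only; peak potentials are area-independent).
#' @param conc_bulk_mol_cm3 Bulk concentration of the initially present redox
#'   form, mol cm^-3.
#' @param grid List of discretization controls: `dE` potential step (V) and
#'   `lambda` the stability ratio D*dt/dx^2 (must be <= 0.5 for the explicit
#'   scheme).
#' @param noise_sd_current Additive Gaussian current noise s.d., A.
#' @param seed Integer seed, required when `noise_sd_current > 0`.
#' @return A validated parameter list of class `"cv_sim_params"`.
#' @export
cv_sim_params <- function(k0_true,
                          alpha_ct_true = 0.5,
                          n_electrons = 1L,
                          D_coeff = 1e-6,
                          E_formal_true = 0.25,
                          E_start = 1.2,
                          E_reverse = -0.2,
                          scan_rate = 0.1,
                          temperature_K = 298.15,
                          electrode_area_cm2 = 0.385,
                          conc_bulk_mol_cm3 = 1e-6,
                          grid = list(dE = 1e-3, lambda = 0.45),
                          noise_sd_current = 0,
                          seed = NULL) {
  check_number(k0_true, "k0_true", positive = TRUE)
  check_number(alpha_ct_true, "alpha_ct_true")
  if (alpha_ct_true <= 0 || alpha_ct_true >= 1) {
    stop_input("`alpha_ct_true` must lie strictly between 0 and 1.")
  }
  check_number(n_electrons, "n_electrons", positive = TRUE)
  check_number(D_coeff, "D_coeff", positive = TRUE)
  check_number(scan_rate, "scan_rate", positive = TRUE)
  check_number(temperature_K, "temperature_K", positive = TRUE)
  check_number(noise_sd_current, "noise_sd_current", nonneg = TRUE)
  if (E_start == E_reverse) {
    stop_input("Degenerate sweep: `E_start` must differ from `E_reverse`.")
  }
  grid <- modifyList(list(dE = 1e-3, lambda = 0.45), grid)
  check_number(grid$dE, "grid$dE", positive = TRUE)
  check_number(grid$lambda, "grid$lambda", positive = TRUE)
  structure(
    list(k0_true = k0_true, alpha_ct_true = alpha_ct_true,
         n_electrons = as.integer(n_electrons), D_coeff = D_coeff,
         E_formal_true = E_formal_true, E_start = E_start,
         E_reverse = E_reverse, scan_rate = scan_rate,
         temperature_K = temperature_K,
         electrode_area_cm2 = electrode_area_cm2,
         conc_bulk_mol_cm3 = conc_bulk_mol_cm3,
         grid = grid, noise_sd_current = noise_sd_current, seed = seed),
    class = "cv_sim_params")
}

#' Simulate a quasi-reversible cyclic voltammogram
#'
#' Explicit finite-difference solution of one-electron Butler-Volmer kinetics
#' with semi-infinite planar diffusion. The species that is thermodynamically
#' stable at `E_start` is taken as the initially present form, so the forward
#' sweep produces one faradaic peak and the reverse sweep its counter-peak.
#' Anodic current is positive.
#'
#' The surface boundary condition couples the Butler-Volmer flux to the
#' diffusive flux; with equal diffusion coefficients the oxidized-form surface
#' concentration is `1 - c_R` in units of the bulk concentration.
#'
#' @param params A [cv_sim_params()] object.
#' @return A [voltammogram()] with the true parameters attached as
#'   `attr(x, "sim_params")`.
#' @examples
#' v <- simulate_voltammogram(cv_sim_params(k0_true = 1, scan_rate = 0.1))
#' detect_redox_peaks(v)
#' @export
simulate_voltammogram <- function(params) {
  stopifnot(inherits(params, "cv_sim_params"))
  p <- params
  if (p$noise_sd_current > 0 && is.null(p$seed)) {
    stop_input("`seed` is required when `noise_sd_current` > 0.")
  }
  lambda <- p$grid$lambda
  if (lambda > 0.5) {
    abort(sprintf(
      paste0("Explicit diffusion scheme unstable: stability ratio ",
             "lambda = D*dt/dx^2 = %.3g exceeds 0.5."), lambda),
      class = c("qbetr_discretization_error", "qbetr_error"))
  }
  dE <- p$grid$dE
  f <- f_over_RT(p$temperature_K) * p$n_electrons
  span <- p$E_reverse - p$E_start
  n_half <- max(2L, ceiling(abs(span) / dE))
  E_fwd <- seq(p$E_start, p$E_reverse, length.out = n_half + 1L)
  E_prog <- c(E_fwd, rev(E_fwd)[-1L])
  n_t <- length(E_prog)

  dt <- abs(span) / n_half / p$scan_rate
  dx <- sqrt(p$D_coeff * dt / lambda)
  n_x <- ceiling(6 * sqrt(lambda * n_t)) + 2L

  # reduced form is stable at low potential
  start_reduced <- p$E_start < p$E_formal_true
  cR <- rep(if (start_reduced) 1 else 0, n_x)
  d_over_dx <- p$D_coeff / dx
  current <- numeric(n_t)
  i_scale <- p$n_electrons * qbet_constants()$F_const *
    p$electrode_area_cm2 * p$conc_bulk_mol_cm3

  for (j in seq_len(n_t)) {
    if (j > 1L) {
      interior <- 2:(n_x - 1L)
      cR[interior] <- cR[interior] +
        lambda * (cR[interior + 1L] - 2 * cR[interior] + cR[interior - 1L])
      # semi-infinite bulk
      cR[n_x] <- if (start_reduced) 1 else 0
    }
    eta <- E_prog[j] - p$E_formal_true
    kf <- p$k0_true * exp(-p$alpha_ct_true * f * eta)        # reduction O -> R
    kb <- p$k0_true * exp((1 - p$alpha_ct_true) * f * eta)   # oxidation R -> O
    # Butler-Volmer flux balanced against a second-order one-sided gradient
    cR[1L] <- (kf + 0.5 * d_over_dx * (4 * cR[2L] - cR[3L])) /
      (kf + kb + 1.5 * d_over_dx)
    current[j] <- i_scale * (kb * cR[1L] - kf * (1 - cR[1L]))
  }

  if (p$noise_sd_current > 0) {
    current <- current + with_local_seed(
      p$seed, rnorm(n_t, sd = p$noise_sd_current))
  }

  out <- voltammogram(
    tibble(potential_V = E_prog, current_A = current),
    scan_rate = p$scan_rate, temperature_K = p$temperature_K,
    label = sprintf("simulated k0=%.3g cm/s", p$k0_true))
  attr(out, "sim_params") <- p
  out
}

#' Simulate a study of voltammograms across scan rates
#'
#' One voltammogram per requested rate, sharing all other true parameters.
#' Noise, when enabled, is seeded per rate by offsetting the base seed so that
#' replicate voltammograms are independent yet the study is reproducible.
#'
#' @param params A [cv_sim_params()] object (its `scan_rate` is ignored).
#' @param rates Distinct positive scan rates, V s^-1.
#' @return A [scan_rate_study()] with rates in ascending order.
#' @export
simulate_scan_rate_study <- function(params, rates) {
  stopifnot(inherits(params, "cv_sim_params"))
  if (length(rates) == 0L || !is.numeric(rates)) {
    stop_input("`rates` must be a non-empty numeric vector.")
  }
  if (any(rates <= 0)) stop_input("All scan rates must be > 0.")
  if (anyDuplicated(rates)) stop_input("Scan rates must be distinct.")
  rates <- sort(rates)
  vgrams <- purrr::imap(rates, function(v, i) {
    p_i <- params
    p_i$scan_rate <- v
    if (!is.null(p_i$seed)) p_i$seed <- p_i$seed + (i - 1L)
    simulate_voltammogram(p_i)
  })
  out <- scan_rate_study(vgrams, label = sprintf(
    "simulated k0=%.3g cm/s", params$k0_true))
  attr(out, "sim_params") <- params
  out
}
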
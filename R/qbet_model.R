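#' Donor charging rate from normalized metabolic activity
#'
#' Inverts the exponential survival model `M(t) = exp(-r_d * t)`:
#' `r_d = -ln(M(t)) / t`. Activity above 1 (a control-normalized well more
#' active than the control) yields a negative rate, which is allowed and
#' flagged downstream, not an error.
#'
#' @param activity Metabolic activity `M(t)` as a fraction of the untreated
#'   control (> 0, vectorized).
#' @param time Exposure time in hours (> 0).
#' @return Charging rate `r_d` in h^-1.
#' @examples
#' charging_rate_from_activity(0.5, 12)   # ln(2)/12
#' @export
charging_rate_from_activity <- function(activity, time) {
  if (any(!is.finite(activity)) || any(activity <= 0)) {
    stop_input("`activity` must be finite and > 0.")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_input("`time` must be finite and > 0.")
  }
  -log(activity) / time
}

#' Metabolic activity predicted by the survival model
#'
#' The closed-form survival solution `M(t) = exp(-r_d * t)`; the exact
#' inverse of [charging_rate_from_activity()].
#'
#' @param r_d Charging rate, h^-1 (vectorized).
#' @param time Time in hours (>= 0).
#' @return Predicted activity fraction.
#' @export
predicted_activity <- function(r_d, time) {
  if (any(time < 0)) stop_input("`time` must be >= 0.")
  exp(-r_d * time)
}

#' Construct a cell-survival state
#'
#' @param alive,dead Non-negative counts (need not be integer).
#' @return A one-row tibble of class `"survival_state"` with columns `alive`,
#'   `dead`, `total`.
#' @export
survival_state <- function(alive, dead = 0) {
  check_number(alive, "alive", nonneg = TRUE)
  check_number(dead, "dead", nonneg = TRUE)
  out <- tibble(alive = alive, dead = dead, total = alive + dead)
  class(out) <- c("survival_state", class(out))
  out
}

#' Evolve a survival state under a constant charging rate
#'
#' Dead cells accrue as the integral of `alive(t) * r_d`; with constant
#' `r_d` the exact update is `alive -> alive * exp(-r_d * dt)`, with the
#' total conserved. Metabolic activity computed from the state,
#' `alive / total`, equals the closed-form `exp(-r_d * t)`.
#'
#' @param state A [survival_state()].
#' @param r_d Charging rate, h^-1.
#' @param dt Time step in hours (>= 0).
#' @return The updated `survival_state`.
#' @export
evolve_survival <- function(state, r_d, dt) {
  stopifnot(inherits(state, "survival_state"))
  if (!is.finite(dt) || dt < 0) stop_input("`dt` must be >= 0.")
  alive <- state$alive * exp(-r_d * dt)
  out <- tibble(alive = alive, dead = state$total - alive,
                total = state$total)
  class(out) <- c("survival_state", class(out))
  out
}

#' PEG linker length from molecular weight
#'
#' Converts a PEG linker mass to a length. The default `"contour"` convention
#' uses the fully extended chain: 0.35 nm per ethylene-oxide monomer of
#' 44.05 Da, i.e. `L = 0.35 * (1000 * mass_kDa / 44.05)` nm.
#'
#' @param linker_mass Linker mass in kDa (> 0, vectorized).
#' @param convention `"contour"` (default) or `"custom"`.
#' @param nm_per_monomer,monomer_mass_Da Conversion factors, used directly
#'   when `convention = "custom"` (and as the contour defaults otherwise).
#' @return Linker length in nm.
#' @examples
#' linker_length_from_mw(2)   # ~15.9 nm
#' @export
linker_length_from_mw <- function(linker_mass,
                                  convention = c("contour", "custom"),
                                  nm_per_monomer = 0.35,
                                  monomer_mass_Da = 44.05) {
  convention <- match.arg(convention)
  if (any(!is.finite(linker_mass)) || any(linker_mass <= 0)) {
    stop_input("`linker_mass` must be finite and > 0 (kDa).")
  }
  check_number(nm_per_monomer, "nm_per_monomer", positive = TRUE)
  check_number(monomer_mass_Da, "monomer_mass_Da", positive = TRUE)
  nm_per_monomer * (1000 * linker_mass / monomer_mass_Da)
}

#' Per-condition donor charging rates from a metabolic dataset
#'
#' Computes `r_d` per replicate via [charging_rate_from_activity()] and then
#' averages within each (cell line, diameter, linker mass) condition --
#' deliberately in that order, matching error bars that report the spread of
#' per-replicate rates rather than the rate of the mean activity.
#'
#' Conditions containing any replicate with activity above 1 keep their
#' (possibly negative) mean rate but are tagged `activity_gain`; conditions
#' whose mean rate is non-positive are marked `usable = FALSE` and should be
#' excluded from barrier fitting. Rows with non-positive activity or time are
#' rejected at ingest.
#'
#' @param dataset A data frame with columns `cell_line`, `diameter_nm`,
#'   `linker_kda`, `time_h`, `activity_fraction`, `replicate` (the layout
#'   written by [simulate_metabolic_dataset()]). An optional
#'   `linker_length_nm` column is carried through; otherwise it is derived
#'   with [linker_length_from_mw()].
#' @param ... Passed to [linker_length_from_mw()].
#' @return A tibble of class `"charging_rates"`, one row per condition:
#'   `cell_line`, `diameter_nm`, `linker_kda`, `linker_length_nm`, `r_d`
#'   (mean, h^-1), `se` (standard error of the mean), `n_replicates`,
#'   `activity_gain`, `usable`.
#' @export
aggregate_charging_rates <- function(dataset, ...) {
  req <- c("cell_line", "diameter_nm", "linker_kda", "time_h",
           "activity_fraction", "replicate")
  missing_cols <- setdiff(req, names(dataset))
  if (length(missing_cols) > 0L) {
    stop_input(sprintf("Missing column(s): %s.",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(dataset$activity_fraction <= 0)) {
    stop_input("All `activity_fraction` values must be > 0.")
  }
  if (any(dataset$time_h <= 0)) {
    stop_input("All `time_h` values must be > 0 for rate extraction.")
  }
  d <- as_tibble(dataset)
  if (!"linker_length_nm" %in% names(d)) {
    d$linker_length_nm <- linker_length_from_mw(d$linker_kda, ...)
  }
  d$r_d_rep <- charging_rate_from_activity(d$activity_fraction, d$time_h)
  out <- d |>
    dplyr::group_by(.data$cell_line, .data$diameter_nm, .data$linker_kda,
                    .data$linker_length_nm) |>
    dplyr::summarise(
      r_d = mean(.data$r_d_rep),
      se = if (dplyr::n() > 1L) sd(.data$r_d_rep) / sqrt(dplyr::n()) else 0,
      n_replicates = dplyr::n(),
      activity_gain = any(.data$activity_fraction > 1),
      .groups = "drop") |>
    dplyr::mutate(usable = .data$r_d > 0)
  if (any(!out$usable)) {
    warn(sprintf(
      "%d condition(s) with non-positive mean r_d tagged unusable for barrier fitting.",
      sum(!out$usable)))
  }
  class(out) <- c("charging_rates", class(out))
  out
}

#' Fit the exponential tunnelling-barrier decay
#'
#' Fits `r_d(L) = beta * exp(-alpha_loc * L)`, the distance decay expected
#' for electron tunnelling through a barrier of width `L` (tunnelling
#' probability proportional to `exp(-alpha * r)` with inverse localization
#' length `alpha`). Estimation is weighted nonlinear least squares
#' (weights `1/se^2` where standard errors are supplied and positive,
#' unweighted otherwise), initialized from the log-linear regression of
#' `ln r_d` on `L`; both estimates are reported.
#'
#' When per-point standard errors are used as weights they are treated as
#' known measurement variances, so parameter standard errors come from the
#' weighted Jacobian without rescaling by the residual variance (the
#' fixed-effect meta-analytic convention). Unweighted fits use the usual
#' residual-variance estimate.
#'
#' @param points A data frame with columns `linker_length_nm` (or `L`), `r_d`
#'   and optionally `se`; a `usable` logical column, when present, filters
#'   rows first. At least 3 points with distinct lengths and positive rates
#'   are required.
#' @param pool_variances When the table also carries `n_replicates` (as
#'   [aggregate_charging_rates()] output does) and this is `TRUE` (default),
#'   per-condition replicate variances are pooled before weighting. Under the
#'   survival model, multiplicative activity noise at a common readout time
#'   gives every condition's per-replicate rate the same variance, so the
#'   pooled estimate carries far more degrees of freedom than each
#'   condition's own few replicates; weighting by raw few-replicate standard
#'   errors both loses efficiency and leaves the reported parameter errors
#'   anti-conservative. Set to `FALSE` to weight by the raw `se` column.
#' @return A list of class `"tunnelling_fit"` with elements `alpha_loc`
#'   (nm^-1), `beta` (h^-1), `alpha_se`, `beta_se`, `r_squared` (untransformed
#'   scale), `n_points`, `method`, `loglinear` (init estimates), `weighted`,
#'   `warnings` and `data`.
#' @examples
#' L <- c(8, 16, 28, 40)
#' fit_barrier_decay(data.frame(linker_length_nm = L,
#'                              r_d = 0.1 * exp(-0.1 * L)))
#' @export
fit_barrier_decay <- function(points, pool_variances = TRUE) {
  d <- as_tibble(points)
  if ("L" %in% names(d) && !"linker_length_nm" %in% names(d)) {
    d$linker_length_nm <- d$L
  }
  if (!all(c("linker_length_nm", "r_d") %in% names(d))) {
    stop_input("`points` needs columns `linker_length_nm` (or `L`) and `r_d`.")
  }
  if ("usable" %in% names(d)) d <- d[d$usable, ]
  d <- d[is.finite(d$r_d) & d$r_d > 0 & is.finite(d$linker_length_nm), ]
  if (nrow(d) < 3L) {
    abort("Fewer than 3 usable points (positive r_d, finite L).",
          class = c("qbetr_fit_error", "qbetr_error"))
  }
  if (length(unique(d$linker_length_nm)) < 3L) {
    abort("At least 3 distinct linker lengths are required.",
          class = c("qbetr_fit_error", "qbetr_error"))
  }
  L <- d$linker_length_nm
  y <- d$r_d
  se_for_weights <- if ("se" %in% names(d)) d$se else NULL
  if (pool_variances && all(c("se", "n_replicates") %in% names(d)) &&
      all(is.finite(d$se)) && any(d$se > 0) && all(d$n_replicates > 1)) {
    df_i <- d$n_replicates - 1
    s2_i <- d$se^2 * d$n_replicates        # per-replicate variances
    s2_pooled <- sum(df_i * s2_i) / sum(df_i)
    se_for_weights <- sqrt(s2_pooled / d$n_replicates)
  }
  weighted <- !is.null(se_for_weights) && all(is.finite(se_for_weights)) &&
    all(se_for_weights > 0)
  w <- if (weighted) 1 / se_for_weights^2 else rep(1, nrow(d))

  ll <- lm(log(y) ~ L)
  alpha0 <- -unname(coef(ll)[2L]) + 0   # + 0 normalizes a -0 slope
  beta0 <- exp(unname(coef(ll)[1L]))
  loglinear <- c(alpha_loc = alpha0, beta = beta0)
  warnings <- character()

  try_nls <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ beta * exp(-alpha * L), start = start, weights = w,
        control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                             maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_nls(list(beta = beta0, alpha = alpha0))
  if (is.null(fit)) {
    fit <- try_nls(list(beta = beta0, alpha = alpha0 * 1.05 + 1e-4))
  }
  if (is.null(fit)) {
    # degenerate surface (for example exactly flat data): report the
    # log-linear solution with delta-method errors
    sm <- suppressWarnings(summary(ll))$coefficients
    est <- c(beta = beta0, alpha = alpha0)
    ses <- c(beta = beta0 * sm[1L, 2L], alpha = sm[2L, 2L])
    method <- "log-linear"
    warnings <- c(warnings,
                  "Nonlinear fit degenerate; log-linear estimates reported.")
    warn(warnings[length(warnings)])
  } else {
    est <- coef(fit)
    vc <- vcov(fit)
    if (weighted) {
      # weights are known inverse variances: drop the residual-variance factor
      s2 <- summary(fit)$sigma^2
      if (is.finite(s2) && s2 > 0) vc <- vc / s2
    }
    ses <- sqrt(pmax(diag(vc), 0))
    method <- "nonlinear"
  }
  fitted_y <- est[["beta"]] * exp(-est[["alpha"]] * L)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - fitted_y)^2) / ss_tot else 1

  if (est[["alpha"]] < 0) {
    warnings <- c(warnings,
                  "alpha_loc < 0: no barrier decay (rate grows with distance).")
    warn(warnings[length(warnings)])
  }
  out <- list(alpha_loc = unname(est[["alpha"]]), beta = unname(est[["beta"]]),
              alpha_se = unname(ses[["alpha"]]), beta_se = unname(ses[["beta"]]),
              r_squared = r2, n_points = nrow(d), method = method,
              loglinear = loglinear, weighted = weighted,
              warnings = warnings, data = d)
  class(out) <- "tunnelling_fit"
  out
}

#' @export
print.tunnelling_fit <- function(x, ...) {
  cat(sprintf(
    "<tunnelling_fit> alpha = %.4g +/- %.2g nm^-1, beta = %.4g +/- %.2g h^-1 (R^2 = %.3f, n = %d%s)\n",
    x$alpha_loc, x$alpha_se, x$beta, x$beta_se, x$r_squared, x$n_points,
    if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' @rdname fit_barrier_decay
#' @param x A `tunnelling_fit`.
#' @param ... Unused.
#' @export
tidy.tunnelling_fit <- function(x, ...) {
  tibble(term = c("alpha_loc", "beta"),
         estimate = c(x$alpha_loc, x$beta),
         std.error = c(x$alpha_se, x$beta_se),
         loglinear = unname(x$loglinear[c("alpha_loc", "beta")]))
}

#' @rdname fit_barrier_decay
#' @export
glance.tunnelling_fit <- function(x, ...) {
  tibble(alpha_loc = x$alpha_loc, beta = x$beta, alpha_se = x$alpha_se,
         beta_se = x$beta_se, r_squared = x$r_squared,
         n_points = x$n_points, weighted = x$weighted,
         method = x$method)
}

#' Maximum classical electron-hop distance per field cycle
#'
#' An electron moving at the interfacial transfer velocity `k0` (cm s^-1) for
#' one cycle of an a.c. field of frequency `f` covers at most `d = k0 / f`,
#' here converted to nanometres. With the rate constant of the
#' bifunctionalized particle (3.75e-3 cm/s) and a 3 MHz drive this bound is
#' 0.0125 nm, i.e. 0.01 nm at one significant figure -- far below any linker
#' length, which is what rules out classical transport.
#'
#' @param k0 Heterogeneous rate constant, cm s^-1 (> 0).
#' @param frequency Field frequency, Hz (> 0).
#' @return A one-row tibble: `k0`, `frequency`, `d_max_nm` (full precision)
#'   and `d_max_nm_1sf` (one significant figure).
#' @examples
#' max_hop_distance(3.75e-3, 3e6)
#' @export
max_hop_distance <- function(k0, frequency) {
  check_number(k0, "k0", positive = TRUE)
  check_number(frequency, "frequency", positive = TRUE)
  d_nm <- k0 / frequency * 1e7   # cm -> nm
  tibble(k0 = k0, frequency = frequency, d_max_nm = d_nm,
         d_max_nm_1sf = signif(d_nm, 1))
}

#' Classical-transport feasibility verdict
#'
#' Classical (non-tunnelling) electron transport across the linker is deemed
#' possible only when the per-cycle hop bound reaches the barrier width:
#' `classical_possible = d_max >= linker_length` (boundary inclusive).
#'
#' @param d_max Maximum hop distance per cycle, nm (> 0); see
#'   [max_hop_distance()].
#' @param linker_length Barrier (linker) length, nm (> 0).
#' @param k0,frequency Optional provenance values echoed into the report.
#' @return A one-row tibble of class `"feasibility_report"`: `k0`,
#'   `frequency`, `d_max_nm`, `linker_length_nm`, `classical_possible`.
#' @export
classical_feasibility <- function(d_max, linker_length,
                                  k0 = NA_real_, frequency = NA_real_) {
  check_number(d_max, "d_max", positive = TRUE)
  check_number(linker_length, "linker_length", positive = TRUE)
  out <- tibble(k0 = k0, frequency = frequency, d_max_nm = d_max,
                linker_length_nm = linker_length,
                classical_possible = d_max >= linker_length)
  class(out) <- c("feasibility_report", class(out))
  out
}
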
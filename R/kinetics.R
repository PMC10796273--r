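#' Locate the anodic and cathodic peaks of a voltammogram
#'
#' Splits the sweep at the potential reversal, subtracts a linear baseline
#' fitted to the leading `baseline_fraction` of each branch (in sweep order),
#' smooths with a centred moving average and takes the extremum: the maximum
#' of the positive-going (anodic) branch and the minimum of the negative-going
#' (cathodic) branch.
#'
#' @param vgram A [voltammogram()].
#' @param smoothing_window Odd integer width of the moving-average smoother;
#'   must be smaller than a fifth of the branch length.
#' @param baseline_fraction Fraction of each branch (from its start, in sweep
#'   order) used to fit the linear baseline.
#' @return A one-row tibble of class `"peak_pair"` with columns `E_pa`, `E_pc`
#'   (V), `i_pa`, `i_pc` (A, baseline-corrected), `delta_Ep = E_pa - E_pc` and
#'   `E_formal = (E_pa + E_pc)/2`.
#' @details A branch whose corrected extremum does not exceed three times the
#'   residual noise s.d. of its baseline region raises a `qbetr_no_peak`
#'   error naming the branch. Ties between equal-height extrema are broken
#'   toward the potential closest to the sweep midpoint, with a warning.
#' @export
detect_redox_peaks <- function(vgram, smoothing_window = 5L,
                               baseline_fraction = 0.1) {
  stopifnot(inherits(vgram, "voltammogram"))
  if (smoothing_window %% 2L != 1L) {
    stop_input("`smoothing_window` must be an odd integer.")
  }
  if (smoothing_window >= nrow(vgram) / 5) {
    stop_input("`smoothing_window` must be below a fifth of the record length.")
  }
  if (baseline_fraction <= 0 || baseline_fraction >= 1) {
    stop_input("`baseline_fraction` must lie in (0, 1).")
  }
  pot <- vgram$potential_V
  cur <- vgram$current_A
  i_rev <- which_reversal(pot)
  branches <- list(seq_len(i_rev), seq(i_rev + 1L, length(pot)))
  mid_E <- (max(pot) + min(pot)) / 2

  one_branch <- function(idx) {
    E <- pot[idx]
    I <- cur[idx]
    anodic <- E[length(E)] > E[1L]
    n_base <- max(2L, floor(baseline_fraction * length(E)))
    base_fit <- lm(I[seq_len(n_base)] ~ E[seq_len(n_base)])
    base <- coef(base_fit)[1L] + coef(base_fit)[2L] * E
    resid_sd <- sd(I[seq_len(n_base)] - base[seq_len(n_base)])
    corr <- smooth_ma(I - base, smoothing_window)
    y <- if (anodic) corr else -corr
    peak_val <- max(y)
    if (!is.finite(peak_val) ||
        peak_val <= 3 * max(resid_sd, .Machine$double.eps)) {
      abort(sprintf("No %s peak above 3x the baseline noise level.",
                    if (anodic) "anodic" else "cathodic"),
            class = c("qbetr_no_peak", "qbetr_error"),
            branch = if (anodic) "anodic" else "cathodic")
    }
    at <- which(y == peak_val)
    if (length(at) > 1L) {
      warn(sprintf("%d equal-height extrema on the %s branch; tie broken %s",
                   length(at), if (anodic) "anodic" else "cathodic",
                   "toward the sweep midpoint."))
      at <- at[which.min(abs(E[at] - mid_E))]
    }
    list(E = E[at], i = corr[at], anodic = anodic)
  }

  res <- lapply(branches, one_branch)
  an <- res[[which(vapply(res, `[[`, logical(1), "anodic"))]]
  ca <- res[[which(!vapply(res, `[[`, logical(1), "anodic"))]]
  out <- tibble(
    E_pa = an$E, E_pc = ca$E, i_pa = an$i, i_pc = ca$i,
    delta_Ep = an$E - ca$E, E_formal = (an$E + ca$E) / 2)
  if (out$delta_Ep <= 0) {
    abort("Peak assignment inverted: anodic peak below cathodic peak.",
          class = c("qbetr_no_peak", "qbetr_error"))
  }
  class(out) <- c("peak_pair", class(out))
  out
}

# centred moving average, shrinking symmetrically at the edges
smooth_ma <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Transfer coefficient from the peak-shift scan-rate regression
#'
#' Fits the linear regression of the peak-to-formal potential difference
#' `Ep - E_formal` (V) on `log10(scan rate)` and converts the slope to the
#' Butler-Volmer transfer coefficient via
#' `alpha = -2.3 * R * T / (slope * n * F)` (cathodic branch; for the anodic
#' branch the slope enters with opposite sign).
#'
#' @param data A data frame with numeric columns `scan_rate` (V s^-1) and
#'   `delta_E` (`Ep - E_formal`, V), one row per scan rate.
#' @param n_electrons Electrons transferred.
#' @param branch `"cathodic"` (default) or `"anodic"`; sets the expected sign
#'   of the slope.
#' @param temperature_K Temperature, kelvin.
#' @return A one-row tibble of class `"transfer_coefficient_fit"` with
#'   `alpha_ct`, `slope` (V per decade), `intercept`, `r_squared`, `branch`,
#'   `n_points` and a `warnings` list-column. A slope of the unexpected sign
#'   yields a warning and `alpha_ct` is reported as the absolute value; values
#'   above 1 are physically suspect and flagged.
#' @examples
#' pts <- data.frame(scan_rate = c(1, 10, 100),
#'                   delta_E = c(0, -0.05908, -0.11816))
#' transfer_coefficient_fit(pts)  # alpha = 1
#' @export
transfer_coefficient_fit <- function(data, n_electrons = 1L,
                                     branch = c("cathodic", "anodic"),
                                     temperature_K = 298.15) {
  branch <- match.arg(branch)
  if (!all(c("scan_rate", "delta_E") %in% names(data))) {
    stop_input("`data` needs columns `scan_rate` and `delta_E`.")
  }
  if (nrow(data) < 3L) {
    stop_input("At least 3 scan rates are required for the regression.")
  }
  if (length(unique(data$scan_rate)) < nrow(data)) {
    stop_input("Scan rates must be distinct.")
  }
  x <- log10(data$scan_rate)
  if (length(unique(x)) < 2L) {
    stop_input("Singular regression: scan rates do not vary.")
  }
  fit <- lm(data$delta_E ~ x)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  ss_tot <- sum((data$delta_E - mean(data$delta_E))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  cc <- qbet_constants()
  alpha <- -cc$decade_factor * cc$R_gas * temperature_K /
    (slope * n_electrons * cc$F_const)
  if (branch == "anodic") alpha <- -alpha
  warnings <- character()
  if (alpha < 0) {
    warnings <- c(warnings, sprintf(
      "Slope has the unexpected sign for the %s branch; |alpha| reported.",
      branch))
    warn(warnings[length(warnings)])
    alpha <- abs(alpha)
  }
  if (alpha > 1.5) {
    warnings <- c(warnings, sprintf(
      paste0("Regression alpha_ct = %.3g clamped to 1.5; the peak-shift ",
             "slope is far from its irreversible asymptote (quasi-",
             "reversible data) and does not identify alpha."), alpha))
    warn(warnings[length(warnings)])
    alpha <- 1.5
  } else if (alpha > 1.001) {
    warnings <- c(warnings,
                  sprintf("alpha_ct = %.3g exceeds 1: physically suspect.",
                          alpha))
    warn(warnings[length(warnings)])
  }
  out <- tibble(alpha_ct = alpha, slope = slope, intercept = intercept,
                r_squared = r2, branch = branch, n_points = nrow(data),
                warnings = list(warnings))
  class(out) <- c("transfer_coefficient_fit", class(out))
  out
}

#' Transfer coefficient from a scan-rate study
#'
#' Runs [detect_redox_peaks()] on every voltammogram of the study and feeds
#' the requested branch's peak-to-formal potential differences to
#' [transfer_coefficient_fit()].
#'
#' @inheritParams transfer_coefficient_fit
#' @param study A [scan_rate_study()] with at least three rates.
#' @param ... Passed on to [detect_redox_peaks()].
#' @return See [transfer_coefficient_fit()].
#' @export
estimate_transfer_coefficient <- function(study, n_electrons = 1L,
                                          branch = c("cathodic", "anodic"),
                                          ...) {
  branch <- match.arg(branch)
  stopifnot(inherits(study, "scan_rate_study"))
  peaks <- study_peak_table(study, ...)
  if (nrow(peaks) < 3L) {
    stop_input("Fewer than 3 voltammograms with detectable peak pairs.")
  }
  delta <- if (branch == "cathodic") {
    peaks$E_pc - peaks$E_formal
  } else {
    peaks$E_pa - peaks$E_formal
  }
  transfer_coefficient_fit(
    tibble(scan_rate = peaks$scan_rate, delta_E = delta),
    n_electrons = n_electrons, branch = branch,
    temperature_K = attr(study$voltammogram[[1L]], "temperature_K"))
}

study_peak_table <- function(study, ...) {
  rows <- purrr::map2(study$voltammogram, study$scan_rate, function(vg, v) {
    pp <- tryCatch(detect_redox_peaks(vg, ...),
                   qbetr_no_peak = function(e) NULL)
    if (is.null(pp)) return(NULL)
    dplyr::mutate(as_tibble(pp), scan_rate = v, .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' Nicholson kinetic parameter from the peak separation
#'
#' The dimensionless kinetic parameter psi computed from the peak separation
#' with the Lavagnini/Klingler-Kochi working function
#' `psi = 2.18 * sqrt(alpha/pi) * exp(-(alpha^2 * F / (R * T)) * n * dEp)`.
#' The function is strictly decreasing in `delta_Ep`. Note this exponential
#' form tracks Nicholson's working curve closely only for well-separated
#' peaks (roughly `delta_Ep` above ~0.13 V for n = 1) and increasingly
#' underestimates psi toward the reversible limit; see the package vignette.
#'
#' @param alpha_ct Transfer coefficient (> 0).
#' @param n_electrons Electrons transferred.
#' @param delta_Ep Peak separation in volts (vectorized). Values above 1.5 V
#'   are rejected as probable millivolt inputs.
#' @param temperature_K Temperature, kelvin.
#' @return psi (dimensionless, > 0).
#' @examples
#' compute_psi(0.5, 1, 0)      # ~0.8697
#' compute_psi(0.5, 1, 0.1)    # ~0.329
#' @export
compute_psi <- function(alpha_ct, n_electrons = 1L, delta_Ep,
                        temperature_K = 298.15) {
  check_number(alpha_ct, "alpha_ct", positive = TRUE)
  if (any(delta_Ep < 0)) {
    stop_input("`delta_Ep` must be >= 0; fix the peak assignment upstream.")
  }
  if (any(delta_Ep > 1.5)) {
    stop_input(paste0("`delta_Ep` above 1.5 V looks like a millivolt value; ",
                      "supply volts."))
  }
  2.18 * sqrt(alpha_ct / pi) *
    exp(-(alpha_ct^2 * f_over_RT(temperature_K)) * n_electrons * delta_Ep)
}

#' Heterogeneous rate constant from psi
#'
#' Inverts `psi = k0 * (pi * D * n * v * F / (R * T))^(-1/2)` to
#' `k0 = psi * sqrt(pi * D * n * v * F / (R * T))`.
#'
#' @param psi Dimensionless kinetic parameter (> 0, vectorized).
#' @param D_coeff Diffusion coefficient, cm^2 s^-1. No default: supply the
#'   value appropriate to the redox species (about 1e-6 cm^2 s^-1 is a
#'   typical literature magnitude for cytochrome c).
#' @param n_electrons Electrons transferred.
#' @param scan_rate Scan rate, V s^-1 (vectorized with `psi`).
#' @param temperature_K Temperature, kelvin.
#' @return k0 in cm s^-1.
#' @examples
#' compute_k0(0.5, D_coeff = 1e-6, scan_rate = 0.1)  # ~1.75e-3
#' @export
compute_k0 <- function(psi, D_coeff, n_electrons = 1L, scan_rate,
                       temperature_K = 298.15) {
  if (missing(D_coeff) || is.null(D_coeff)) {
    abort(paste0("`D_coeff` is required: supply the diffusion coefficient ",
                 "(cm^2/s) of the redox species."),
          class = c("qbetr_config_error", "qbetr_error"))
  }
  check_number(D_coeff, "D_coeff", positive = TRUE)
  if (any(psi <= 0) || any(scan_rate <= 0)) {
    stop_input("`psi` and `scan_rate` must be > 0.")
  }
  psi * sqrt(pi * D_coeff * n_electrons * scan_rate *
               f_over_RT(temperature_K))
}

#' Full peak-separation kinetics analysis of a scan-rate study
#'
#' Detects peak pairs at every scan rate, determines the transfer coefficient
#' once from the peak-shift regression (both branches are fitted; the
#' `branch` argument selects which feeds the working function), computes psi
#' from each peak separation and converts each to a heterogeneous rate
#' constant, reporting their mean and standard deviation.
#'
#' Voltammograms with `delta_Ep < 0.061 / n` V are excluded from the rate
#' estimate with a "near-reversible" warning: below that separation the
#' exponential working function has no sensitivity to kinetics. The warning
#' list also records that the working function remains a sizeable
#' underestimate until peaks are well separated.
#'
#' @param study A [scan_rate_study()].
#' @param D_coeff Diffusion coefficient, cm^2 s^-1 (required).
#' @param n_electrons Electrons transferred.
#' @param alpha_ct Optional transfer coefficient to use in the working
#'   function. When `NULL` (default) it is estimated from the study via the
#'   peak-shift regression on `branch`. Supplying the independently known
#'   value is recommended in the quasi-reversible regime, where the
#'   peak-shift slope is still far from its irreversible asymptote and the
#'   regression estimate is biased.
#' @param branch Branch for the transfer-coefficient regression.
#' @param ... Passed to [detect_redox_peaks()].
#' @return A list of class `"kinetics_result"`: `per_rate` tibble
#'   (`scan_rate`, `delta_Ep`, `E_formal`, `psi`, `k0`, `used`), `alpha_fit`
#'   and `alpha_fit_other` (both branches), `alpha_ct_used`, `k0_mean`,
#'   `k0_sd`, `D_used`, `n_used`, `temperature_K` and `warnings`.
#' @export
analyze_study <- function(study, D_coeff, n_electrons = 1L, alpha_ct = NULL,
                          branch = c("cathodic", "anodic"), ...) {
  branch <- match.arg(branch)
  stopifnot(inherits(study, "scan_rate_study"))
  if (missing(D_coeff) || is.null(D_coeff)) {
    abort(paste0("`D_coeff` is required: supply the diffusion coefficient ",
                 "(cm^2/s) used in the rate-constant equation."),
          class = c("qbetr_config_error", "qbetr_error"))
  }
  peaks <- study_peak_table(study, ...)
  if (is.null(peaks) || nrow(peaks) < 3L) {
    abort("Fewer than 3 voltammograms with usable peak pairs.",
          class = c("qbetr_analysis_error", "qbetr_error"))
  }
  temperature_K <- attr(study$voltammogram[[1L]], "temperature_K")
  warnings <- character()

  fit_branch <- function(br) {
    delta <- if (br == "cathodic") {
      peaks$E_pc - peaks$E_formal
    } else {
      peaks$E_pa - peaks$E_formal
    }
    withCallingHandlers(
      transfer_coefficient_fit(
        tibble(scan_rate = peaks$scan_rate, delta_E = delta),
        n_electrons = n_electrons, branch = br,
        temperature_K = temperature_K),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  alpha_fit <- fit_branch(branch)
  alpha_fit_other <- fit_branch(setdiff(c("cathodic", "anodic"), branch))
  if (is.null(alpha_ct)) {
    alpha_used <- alpha_fit$alpha_ct
    warnings <- c(warnings, unlist(alpha_fit$warnings))
  } else {
    check_number(alpha_ct, "alpha_ct", positive = TRUE)
    alpha_used <- alpha_ct
  }

  usable <- peaks$delta_Ep >= 0.061 / n_electrons
  if (any(!usable)) {
    warnings <- c(warnings, sprintf(
      paste0("%d voltammogram(s) with delta_Ep < %.0f mV excluded: ",
             "near-reversible, psi working form invalid."),
      sum(!usable), 61 / n_electrons))
  }
  if (!any(usable)) {
    abort("All peak separations are near-reversible (< 61/n mV); no k0.",
          class = c("qbetr_analysis_error", "qbetr_error"))
  }
  psi <- compute_psi(alpha_used, n_electrons, peaks$delta_Ep, temperature_K)
  k0 <- compute_k0(psi, D_coeff, n_electrons, peaks$scan_rate, temperature_K)
  per_rate <- tibble(scan_rate = peaks$scan_rate, delta_Ep = peaks$delta_Ep,
                     E_formal = peaks$E_formal, psi = psi, k0 = k0,
                     used = usable)
  out <- list(per_rate = per_rate, alpha_fit = alpha_fit,
              alpha_fit_other = alpha_fit_other,
              alpha_ct_used = alpha_used,
              k0_mean = mean(k0[usable]),
              k0_sd = if (sum(usable) > 1L) sd(k0[usable]) else NA_real_,
              D_used = D_coeff, n_used = as.integer(n_electrons),
              temperature_K = temperature_K, warnings = warnings)
  class(out) <- "kinetics_result"
  out
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(
    "<kinetics_result> k0 = %.3g +/- %.3g cm/s over %d/%d scan rates (alpha = %.3g)\n",
    x$k0_mean, x$k0_sd, sum(x$per_rate$used), nrow(x$per_rate),
    x$alpha_ct_used))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' @rdname analyze_study
#' @param x A `kinetics_result`.
#' @export
tidy.kinetics_result <- function(x, ...) x$per_rate

#' @rdname analyze_study
#' @export
glance.kinetics_result <- function(x, ...) {
  tibble(k0_mean = x$k0_mean, k0_sd = x$k0_sd,
         alpha_ct_used = x$alpha_ct_used,
         alpha_r_squared = x$alpha_fit$r_squared,
         n_rates = nrow(x$per_rate), n_used = sum(x$per_rate$used),
         D_used = x$D_used, n_electrons = x$n_used,
         temperature_K = x$temperature_K,
         n_warnings = length(x$warnings))
}
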
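# Shared fixtures, built in code at test time.

# a standard noiseless simulated study for kinetics tests
sim_study <- function(k0, rates = c(0.1, 0.2, 0.5, 1, 2), ...) {
  simulate_scan_rate_study(cv_sim_params(k0_true = k0, ...), rates)
}

peak_sep <- function(k0, v, ...) {
  vg <- simulate_voltammogram(cv_sim_params(k0_true = k0, scan_rate = v, ...))
  detect_redox_peaks(vg)$delta_Ep
}

# triangular potential program with arbitrary current
triangle_vgram <- function(current, E_start = 1.2, E_reverse = -0.2,
                           scan_rate = 0.1) {
  n_half <- (length(current) - 1L) %/% 2L
  pot <- c(seq(E_start, E_reverse, length.out = n_half + 1L),
           seq(E_reverse, E_start, length.out = length(current) - n_half)[-1L])
  voltammogram(data.frame(potential_V = pot, current_A = current),
               scan_rate = scan_rate)
}

gaussian_spectrum <- function(centers, amps, widths = 20, sign = 1,
                              range = c(400, 900), step = 1, baseline = 0.1,
                              kind = "scattering", label = "") {
  wl <- seq(range[1], range[2], by = step)
  intensity <- rep(baseline, length(wl))
  sign <- rep_len(sign, length(centers))
  widths <- rep_len(widths, length(centers))
  for (i in seq_along(centers)) {
    intensity <- intensity + sign[i] * amps[i] *
      exp(-(wl - centers[i])^2 / (2 * widths[i]^2))
  }
  spectrum(wl, intensity, kind = kind, label = label)
}
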
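#' Construct an optical spectrum
#'
#' @param wavelength Strictly ascending wavelengths, nm (>= 20 samples).
#' @param intensity Finite intensities, arbitrary units, same length.
#' @param kind `"scattering"` or `"absorbance"`.
#' @param label Free-text label.
#' @return A tibble of class `"spectrum"` with columns `wavelength_nm`,
#'   `intensity`.
#' @export
spectrum <- function(wavelength, intensity,
                     kind = c("scattering", "absorbance"), label = "") {
  kind <- match.arg(kind)
  if (length(wavelength) != length(intensity)) {
    stop_input("`wavelength` and `intensity` must have the same length.")
  }
  if (length(wavelength) < 20L) {
    stop_input("A spectrum needs at least 20 samples.")
  }
  if (any(diff(wavelength) <= 0)) {
    stop_input("`wavelength` must be strictly ascending.")
  }
  if (any(!is.finite(intensity))) {
    stop_input("All intensities must be finite.")
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength),
                intensity = as.numeric(intensity))
  attr(out, "kind") <- kind
  attr(out, "label") <- label
  class(out) <- c("spectrum", class(out))
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %d points, %g-%g nm%s\n", attr(x, "kind"),
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              if (nzchar(attr(x, "label"))) {
                paste0(" [", attr(x, "label"), "]")
              } else ""))
  invisible(x)
}

spectrum_like <- function(template, wavelength, intensity) {
  spectrum(wavelength, intensity, kind = attr(template, "kind"),
           label = attr(template, "label"))
}

#' Parameters for the optical-spectrum generator
#'
#' Spectra are rendered as a constant baseline plus signed Gaussian bands
#' plus seeded Gaussian noise. Default band centres sit at the positions
#' characteristic of functionalized 100 nm gold particles on an ITO
#' substrate: the substrate line near 465 nm, the protein/porphyrin feature
#' near 568 nm and the coating-shifted plasmon resonance near 711 nm (the
#' bare-particle plasmon sits at 612 nm).
#'
#' @param bands A data frame with columns `center_nm`, `width_nm`,
#'   `amplitude`, `sign` (+1 or -1), one row per band.
#' @param baseline Constant baseline, a.u.
#' @param wavelength_range Length-2 numeric, min < max (nm).
#' @param step Grid step, nm (> 0).
#' @param noise_sd Additive noise s.d., a.u.
#' @param kind Spectrum kind.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A validated list of class `"spectrum_sim_params"`.
#' @export
spectrum_sim_params <- function(bands = default_scattering_bands(),
                                baseline = 0.05,
                                wavelength_range = c(400, 900),
                                step = 1,
                                noise_sd = 0,
                                kind = c("scattering", "absorbance"),
                                seed = NULL) {
  kind <- match.arg(kind)
  bands <- as_tibble(bands)
  req <- c("center_nm", "width_nm", "amplitude", "sign")
  if (nrow(bands) > 0L && !all(req %in% names(bands))) {
    stop_input(sprintf("`bands` needs columns %s.", paste(req, collapse = ", ")))
  }
  if (nrow(bands) > 0L && any(bands$width_nm <= 0)) {
    stop_input("Band widths must be > 0.")
  }
  if (nrow(bands) > 0L && !all(bands$sign %in% c(-1, 1))) {
    stop_input("Band signs must be +1 or -1.")
  }
  if (length(wavelength_range) != 2L ||
      wavelength_range[1] >= wavelength_range[2]) {
    stop_input("`wavelength_range` must be (min, max) with min < max.")
  }
  check_number(step, "step", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(
    list(bands = bands, baseline = baseline,
         wavelength_range = as.numeric(wavelength_range), step = step,
         noise_sd = noise_sd, kind = kind, seed = seed),
    class = "spectrum_sim_params")
}

#' Characteristic scattering bands of functionalized 100 nm gold particles
#'
#' @param functionalized If `TRUE` (default), bands at 465, 568 and 711 nm
#'   (substrate, redox-protein feature, coating-shifted plasmon); if `FALSE`,
#'   the bare-particle set with the plasmon at 612 nm.
#' @return A band table for [spectrum_sim_params()].
#' @export
default_scattering_bands <- function(functionalized = TRUE) {
  if (functionalized) {
    tibble(center_nm = c(465, 568, 711),
           width_nm = c(18, 40, 45),
           amplitude = c(0.35, 0.55, 1.0),
           sign = c(1, 1, 1))
  } else {
    tibble(center_nm = c(465, 612),
           width_nm = c(18, 50),
           amplitude = c(0.35, 1.0),
           sign = c(1, 1))
  }
}

#' Simulate an optical spectrum
#'
#' Renders `baseline + sum(sign * amplitude * Gaussian(center, width))` on
#' the requested grid, plus seeded Gaussian noise. Bands centred outside the
#' wavelength range are still rendered (their in-range tail) with a warning.
#'
#' @param params A [spectrum_sim_params()] object.
#' @return A [spectrum()].
#' @examples
#' s <- simulate_spectrum(spectrum_sim_params())
#' peak_max(s, window = c(550, 800))   # ~711 nm
#' @export
simulate_spectrum <- function(params) {
  stopifnot(inherits(params, "spectrum_sim_params"))
  p <- params
  wl <- seq(p$wavelength_range[1], p$wavelength_range[2], by = p$step)
  intensity <- rep(p$baseline, length(wl))
  if (nrow(p$bands) > 0L) {
    outside <- p$bands$center_nm < p$wavelength_range[1] |
      p$bands$center_nm > p$wavelength_range[2]
    if (any(outside)) {
      warn(sprintf("%d band(s) centred outside the wavelength range %s",
                   sum(outside), "are rendered truncated."))
    }
    for (i in seq_len(nrow(p$bands))) {
      b <- p$bands[i, ]
      intensity <- intensity + b$sign * b$amplitude *
        exp(-(wl - b$center_nm)^2 / (2 * b$width_nm^2))
    }
  }
  if (p$noise_sd > 0) {
    intensity <- intensity +
      with_local_seed(p$seed, rnorm(length(wl), sd = p$noise_sd))
  }
  out <- spectrum(wl, intensity, kind = p$kind, label = "simulated")
  attr(out, "sim_params") <- p
  out
}
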
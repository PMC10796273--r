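#' Resample two spectra onto a common wavelength grid
#'
#' Linearly interpolates both spectra onto their overlapping wavelength
#' range, sampled at the finer of the two native steps. No extrapolation is
#' performed.
#'
#' @param a,b [spectrum()] objects with overlapping ranges.
#' @return A list of the two resampled spectra.
#' @export
resample_to_common_grid <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  lo <- max(min(a$wavelength_nm), min(b$wavelength_nm))
  hi <- min(max(a$wavelength_nm), max(b$wavelength_nm))
  if (lo >= hi) {
    stop_input("Wavelength ranges are disjoint: no common grid.")
  }
  step <- min(stats::median(diff(a$wavelength_nm)),
              stats::median(diff(b$wavelength_nm)))
  if (identical(a$wavelength_nm, b$wavelength_nm)) {
    return(list(a = a, b = b))
  }
  grid <- seq(lo, hi, by = step)
  interp <- function(s) {
    spectrum_like(s, grid,
                  approx(s$wavelength_nm, s$intensity, xout = grid)$y)
  }
  list(a = interp(a), b = interp(b))
}

normalize_intensity <- function(intensity,
                                normalization = c("max", "none", "area"),
                                wavelength = NULL) {
  normalization <- match.arg(normalization)
  switch(normalization,
         none = intensity,
         max = {
           m <- max(abs(intensity))
           if (m == 0) intensity else intensity / m
         },
         area = {
           # trapezoidal integral of |I| over wavelength
           a <- sum(diff(wavelength) *
                      (abs(intensity[-1]) + abs(head(intensity, -1))) / 2)
           if (a == 0) intensity else intensity / a
         })
}

#' Difference spectrum between two spectra of the same kind
#'
#' Resamples both spectra onto their common grid, normalizes each (per-
#' spectrum maximum by default, `none` or trapezoidal `area` selectable) and
#' subtracts: `delta = minuend - subtrahend`. Swapping the operands negates
#' the result exactly.
#'
#' @param minuend,subtrahend [spectrum()] objects of the same kind.
#' @param normalization `"max"` (default), `"none"` or `"area"`.
#' @return A tibble of class `"difference_spectrum"` with columns
#'   `wavelength_nm`, `delta`; operand labels and the normalization mode are
#'   stored as attributes.
#' @export
difference_spectrum <- function(minuend, subtrahend,
                                normalization = c("max", "none", "area")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(minuend, "spectrum"), inherits(subtrahend, "spectrum"))
  if (!identical(attr(minuend, "kind"), attr(subtrahend, "kind"))) {
    stop_input("Cannot subtract spectra of different kinds.")
  }
  rs <- resample_to_common_grid(minuend, subtrahend)
  ia <- normalize_intensity(rs$a$intensity, normalization,
                            rs$a$wavelength_nm)
  ib <- normalize_intensity(rs$b$intensity, normalization,
                            rs$b$wavelength_nm)
  out <- tibble(wavelength_nm = rs$a$wavelength_nm, delta = ia - ib)
  attr(out, "minuend_label") <- attr(minuend, "label")
  attr(out, "subtrahend_label") <- attr(subtrahend, "label")
  attr(out, "normalization") <- normalization
  attr(out, "kind") <- attr(minuend, "kind")
  class(out) <- c("difference_spectrum", class(out))
  out
}

# topographic prominence of a local extremum at index i of y (maxima of y)
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (y[j] > y[i]) break
    left_min <- min(left_min, y[j])
  }
  right_min <- y[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (y[j] > y[i]) break
    right_min <- min(right_min, y[j])
  }
  y[i] - max(left_min, right_min)
}

#' Detect quantized dips or peaks in a difference spectrum
#'
#' Finds local extrema of the requested polarity whose topographic
#' prominence reaches `min_prominence`, reporting each at its grid point,
#' sorted by prominence (descending). An empty result is valid.
#'
#' @param ds A [difference_spectrum()].
#' @param min_prominence Minimum prominence, a.u. (> 0).
#' @param polarity `"dip"` (default; minima of `delta`) or `"peak"`.
#' @return A tibble of class `"spectral_features"` with columns
#'   `wavelength_nm`, `depth_or_height` (the signed `delta` at the extremum),
#'   `prominence`, `polarity`.
#' @export
detect_quantized_features <- function(ds, min_prominence,
                                      polarity = c("dip", "peak")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(ds, "difference_spectrum"))
  check_number(min_prominence, "min_prominence", positive = TRUE)
  y <- if (polarity == "dip") -ds$delta else ds$delta
  n <- length(y)
  is_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i - 1L] else -Inf
    right <- if (i < n) y[i + 1L] else -Inf
    y[i] > left && y[i] >= right   # plateaus credited to their left edge
  }, logical(1)))
  feats <- purrr::map(is_max, function(i) {
    prom <- peak_prominence(y, i)
    if (prom < min_prominence) return(NULL)
    tibble(wavelength_nm = ds$wavelength_nm[i],
           depth_or_height = ds$delta[i],
           prominence = prom, polarity = polarity)
  })
  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0L) {
    out <- tibble(wavelength_nm = numeric(), depth_or_height = numeric(),
                  prominence = numeric(), polarity = character())
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$prominence))
  class(out) <- c("spectral_features", class(out))
  out
}

#' Wavelength of the intensity maximum inside a window
#'
#' Smooths the windowed intensities with a centred 5-point moving average,
#' then reports the wavelength of the maximum. Ties (for example a constant
#' spectrum) are broken toward the window centre with a "no distinct peak"
#' warning. Adding a constant baseline does not change the result.
#'
#' @param s A [spectrum()].
#' @param window Length-2 numeric `(min, max)` in nm; must overlap the grid
#'   with at least 5 samples.
#' @return The peak wavelength, nm.
#' @examples
#' s <- simulate_spectrum(spectrum_sim_params())
#' peak_max(s, c(650, 800))
#' @export
peak_max <- function(s, window) {
  stopifnot(inherits(s, "spectrum"))
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_input("`window` must be (min, max) with min < max.")
  }
  idx <- which(s$wavelength_nm >= window[1] & s$wavelength_nm <= window[2])
  if (length(idx) < 5L) {
    stop_input("Window overlaps fewer than 5 grid samples.")
  }
  wl <- s$wavelength_nm[idx]
  sm <- smooth_ma(s$intensity[idx], 5L)
  peak <- max(sm)
  at <- which(sm >= peak - .Machine$double.eps * max(1, abs(peak)))
  if (length(at) > 1L) {
    center <- mean(window)
    if (length(at) == length(sm)) {
      warn("No distinct peak in window; tie broken toward the window centre.")
    }
    at <- at[which.min(abs(wl[at] - center))]
  }
  wl[at]
}

#' Soret-band redox call from pre/post absorbance spectra
#'
#' Locates the Soret maximum of both spectra inside the search window and
#' classifies the shift `post - pre`: a blueshift at or beyond the threshold
#' calls the haem oxidized, a redshift of the same size calls it reduced,
#' anything smaller is unchanged.
#'
#' @param pre,post Absorbance [spectrum()] objects covering the window.
#' @param threshold Call threshold in nm (default 2).
#' @param window Soret search window, nm (default 380-450).
#' @return A one-row tibble of class `"redox_call"`: `soret_pre_nm`,
#'   `soret_post_nm`, `shift_nm`, `call`, `threshold_nm`.
#' @export
soret_shift_call <- function(pre, post, threshold = 2,
                             window = c(380, 450)) {
  stopifnot(inherits(pre, "spectrum"), inherits(post, "spectrum"))
  if (!identical(attr(pre, "kind"), "absorbance") ||
      !identical(attr(post, "kind"), "absorbance")) {
    stop_input("Soret calling needs absorbance spectra.")
  }
  check_number(threshold, "threshold", positive = TRUE)
  covers <- function(s) {
    min(s$wavelength_nm) <= window[1] && max(s$wavelength_nm) >= window[2]
  }
  if (!covers(pre) || !covers(post)) {
    stop_input(sprintf("Both spectra must cover the Soret window %g-%g nm.",
                       window[1], window[2]))
  }
  p0 <- peak_max(pre, window)
  p1 <- peak_max(post, window)
  shift <- p1 - p0
  call <- if (shift <= -threshold) {
    "oxidized"
  } else if (shift >= threshold) {
    "reduced"
  } else {
    "unchanged"
  }
  out <- tibble(soret_pre_nm = p0, soret_post_nm = p1, shift_nm = shift,
                call = call, threshold_nm = threshold)
  class(out) <- c("redox_call", class(out))
  out
}
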
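#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: the current-potential
#' trace of a voltammogram, intensity against wavelength for spectra and
#' difference spectra (detected features can be overlaid), the peak
#' separations and per-rate rate constants of a kinetics result, and the
#' charging-rate points with the fitted exponential barrier decay.
#'
#' @param object The object to plot.
#' @param features Optional `spectral_features` tibble overlaid as vertical
#'   lines (difference spectra only).
#' @param ... Unused.
#' @return A `ggplot`.
#' @name qbetr-autoplot
NULL

#' @rdname qbetr-autoplot
#' @export
autoplot.voltammogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$potential_V, 1e6 * .data$current_A)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Potential (V)", y = "Current (µA)",
                  title = sprintf("%g V/s", attr(object, "scan_rate"))) +
    ggplot2::theme_minimal()
}

#' @rdname qbetr-autoplot
#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wavelength_nm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Intensity (a.u.)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @rdname qbetr-autoplot
#' @export
autoplot.difference_spectrum <- function(object, features = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$wavelength_nm, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = expression(Delta ~ "(a.u.)")) +
    ggplot2::theme_minimal()
  if (!is.null(features) && nrow(features) > 0L) {
    p <- p + ggplot2::geom_vline(
      data = as_tibble(features),
      ggplot2::aes(xintercept = .data$wavelength_nm),
      linetype = 3, colour = "firebrick")
  }
  p
}

#' @rdname qbetr-autoplot
#' @export
autoplot.kinetics_result <- function(object, ...) {
  ggplot2::ggplot(object$per_rate,
                  ggplot2::aes(log10(.data$scan_rate),
                               1000 * .data$delta_Ep,
                               colour = .data$used)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(log[10] ~ "scan rate (V/s)"),
                  y = expression(Delta * E[p] ~ "(mV)"),
                  colour = "used for k0") +
    ggplot2::theme_minimal()
}

#' @rdname qbetr-autoplot
#' @export
autoplot.tunnelling_fit <- function(object, ...) {
  d <- object$data
  L_grid <- seq(min(d$linker_length_nm), max(d$linker_length_nm),
                length.out = 200)
  curve <- tibble(linker_length_nm = L_grid,
                  r_d = object$beta * exp(-object$alpha_loc * L_grid))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$linker_length_nm, .data$r_d)) +
    ggplot2::geom_line(data = curve, colour = "black") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "Linker length L (nm)",
                  y = expression(r[d] ~ (h^-1)),
                  subtitle = sprintf(
                    "alpha = %.3g nm^-1, beta = %.3g h^-1, R^2 = %.3f",
                    object$alpha_loc, object$beta, object$r_squared)) +
    ggplot2::theme_minimal()
  if ("se" %in% names(d) && any(d$se > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r_d - .data$se,
                   ymax = .data$r_d + .data$se), width = 0.5)
  }
  p
}
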
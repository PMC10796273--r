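#' Construct a voltammogram object
#'
#' A voltammogram is a tibble with columns `potential_V` and `current_A`
#' recorded along a triangular potential program (one reversal), carrying the
#' scan rate and temperature as attributes. Current follows the convention
#' that anodic (oxidation) current is positive.
#'
#' @param data A data frame with numeric columns `potential_V` and `current_A`.
#' @param scan_rate Potential sweep rate in V s^-1 (> 0).
#' @param temperature_K Temperature in kelvin; defaults to 298.15.
#' @param label Free-text label.
#' @return A tibble of class `"voltammogram"`.
#' @export
voltammogram <- function(data, scan_rate, temperature_K = 298.15, label = "") {
  if (!is.data.frame(data) ||
      !all(c("potential_V", "current_A") %in% names(data))) {
    stop_input("A voltammogram needs columns `potential_V` and `current_A`.")
  }
  pot <- data$potential_V
  cur <- data$current_A
  if (!is.numeric(pot) || !is.numeric(cur) || anyNA(pot) || anyNA(cur)) {
    stop_input("`potential_V` and `current_A` must be numeric without NAs.")
  }
  if (length(pot) < 50L) {
    stop_input("A voltammogram needs at least 50 samples.")
  }
  check_number(scan_rate, "scan_rate", positive = TRUE)
  check_number(temperature_K, "temperature_K", positive = TRUE)
  n_rev <- n_reversals(pot)
  if (n_rev != 1L) {
    stop_input(sprintf(
      "Potential program must have exactly one reversal (found %d).", n_rev))
  }
  out <- tibble(potential_V = pot, current_A = cur)
  attr(out, "scan_rate") <- scan_rate
  attr(out, "temperature_K") <- temperature_K
  attr(out, "label") <- label
  class(out) <- c("voltammogram", class(out))
  out
}

n_reversals <- function(potential) {
  dE <- diff(potential)
  dE <- dE[dE != 0]
  if (length(dE) < 2L) return(0L)
  sum(diff(sign(dE)) != 0)
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf(
    "<voltammogram> %d points, %g V/s, %.4g to %.4g V%s\n",
    nrow(x), attr(x, "scan_rate"),
    x$potential_V[1], x$potential_V[which_reversal(x$potential_V)],
    if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else ""))
  NextMethod()
}

# index of the single turning point
which_reversal <- function(potential) {
  dE <- sign(diff(potential))
  dE[dE == 0] <- NA
  first <- dE[!is.na(dE)][1]
  idx <- which(!is.na(dE) & dE != first)[1]
  if (is.na(idx)) length(potential) else idx
}

#' Bundle voltammograms recorded at different scan rates
#'
#' @param voltammograms A list of [voltammogram()] objects with distinct scan
#'   rates. Stored in ascending scan-rate order.
#' @param label Shared free-text label.
#' @return A tibble of class `"scan_rate_study"` with columns `scan_rate`
#'   (V s^-1) and `voltammogram` (list-column). Studies with fewer than three
#'   rates are flagged (`attr(x, "sufficient_for_regression")` is `FALSE`):
#'   the transfer-coefficient regression needs at least three scan rates.
#' @export
scan_rate_study <- function(voltammograms, label = "") {
  if (!is.list(voltammograms) || length(voltammograms) == 0L) {
    stop_input("`voltammograms` must be a non-empty list of voltammograms.")
  }
  ok <- vapply(voltammograms, inherits, logical(1), "voltammogram")
  if (!all(ok)) stop_input("All elements must be voltammogram objects.")
  rates <- vapply(voltammograms, attr, numeric(1), "scan_rate")
  if (anyDuplicated(rates)) {
    stop_input("Scan rates must be distinct across the study.")
  }
  ord <- order(rates)
  out <- tibble(scan_rate = rates[ord], voltammogram = voltammograms[ord])
  attr(out, "label") <- label
  attr(out, "sufficient_for_regression") <- length(rates) >= 3L
  class(out) <- c("scan_rate_study", class(out))
  out
}

#' @export
print.scan_rate_study <- function(x, ...) {
  cat(sprintf("<scan_rate_study> %d scan rates: %s V/s%s\n",
              nrow(x), paste(signif(x$scan_rate, 3), collapse = ", "),
              if (!attr(x, "sufficient_for_regression")) {
                " (insufficient for transfer-coefficient regression)"
              } else ""))
  invisible(x)
}
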
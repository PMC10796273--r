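#' Physical constants used in the electrochemical working equations
#'
#' Returns the fixed constants entering the peak-separation analysis: the
#' Faraday constant `F` (96485 C mol^-1), the gas constant `R`
#' (8.314 J mol^-1 K^-1) and the `decade_factor` 2.3 that converts natural to
#' decadic logarithms in the transfer-coefficient slope equation. The decade
#' factor is deliberately 2.3 (not 2.303) so that hand checks against the
#' working equations in their usual printed form agree digit for digit.
#'
#' @return A named list with elements `F_const`, `R_gas` and `decade_factor`.
#' @examples
#' qbet_constants()
#' @export
qbet_constants <- function() {
  list(F_const = 96485, R_gas = 8.314, decade_factor = 2.3)
}

# F/(R*T) in V^-1; ~38.924 V^-1 at 298.15 K
f_over_RT <- function(temperature_K) {
  cc <- qbet_constants()
  cc$F_const / (cc$R_gas * temperature_K)
}

stop_input <- function(msg, class = "qbetr_input_error", ...) {
  abort(msg, class = c(class, "qbetr_error"), ...)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_input(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    stop_input(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

# Evaluate `expr` under a private RNG stream; the global .Random.seed is
# untouched. All generator randomness flows through here from explicit seeds.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    stop_input("A `seed` is required for stochastic generation.")
  }
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
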
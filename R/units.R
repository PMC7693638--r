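#' Unit conversions for pressures, flows and pump frequencies
#'
#' The package works in SI internally (Pa, m, m^3/s) but instruments and
#' protocols in this field speak mbar, mmHg, uL/min and breaths per minute.
#' These helpers convert between them. 1 mbar = 100 Pa exactly;
#' 1 mmHg = 133.322 Pa.
#'
#' @param p pressure value(s).
#' @param q flow value(s).
#' @param rate breathing rate in breaths per minute (> 0).
#' @param f frequency in Hz (> 0).
#' @param digits rounding used for display-style output of [bpm_to_hz()].
#'
#' @return Numeric vector of converted values.
#' @name units
NULL

MBAR_PER_PA <- 0.01
MMHG_PER_MBAR <- 100 / 133.322 # = 0.7500617 mmHg per mbar
UL_MIN_PER_M3_S <- 6e10

#' @rdname units
#' @export
mbar_to_pa <- function(p) p * 100

#' @rdname units
#' @export
pa_to_mbar <- function(p) p * MBAR_PER_PA

#' @rdname units
#' @export
mbar_to_mmhg <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("pressure must be >= 0 mbar", call. = FALSE)
  p * MMHG_PER_MBAR
}

#' @rdname units
#' @export
mmhg_to_mbar <- function(p) p / MMHG_PER_MBAR

#' @rdname units
#' @export
ul_min_to_m3_s <- function(q) q / UL_MIN_PER_M3_S

#' @rdname units
#' @export
m3_s_to_ul_min <- function(q) q * UL_MIN_PER_M3_S

#' @rdname units
#' @export
bpm_to_hz <- function(rate, digits = NULL) {
  if (any(rate <= 0)) stop("breathing rate must be > 0", call. = FALSE)
  f <- rate / 60
  if (!is.null(digits)) f <- round(f, digits)
  f
}

#' @rdname units
#' @export
hz_to_bpm <- function(f) {
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  f * 60
}
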
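#' Unit conversion helpers
#'
#' All lengths, flows and pressures are stored internally in SI units
#' (metres, m^3/s, Pa). Constructors and reports use the micro-scale units
#' conventional in chip design: micrometres for features, microlitres or
#' nanolitres per minute for perfusion flows, millibar for loading suction
#' and centimetres for capillary tubing. Conversion is centralised here so
#' no magic factors appear elsewhere.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
#' @examples
#' ulmin_to_m3s(9.5)      # perfusion flow in m^3/s
#' m3s_to_nlmin(6.25e-12) # 375 nl/min
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
ulmin_to_m3s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
m3s_to_ulmin <- function(x) x * 60e9

#' @rdname units
#' @export
nlmin_to_m3s <- function(x) x * 1e-12 / 60

#' @rdname units
#' @export
m3s_to_nlmin <- function(x) x * 60e12

#' @rdname units
#' @export
mbar_to_pa <- function(x) x * 100

#' @rdname units
#' @export
cm_to_m <- function(x) x * 1e-2

# standard gravity, m/s^2 (hydrostatic disturbance heads)
.g0 <- 9.81

stopifnot_positive <- function(..., .finite = TRUE) {
  vals <- list(...)
  nms <- sapply(substitute(list(...))[-1], deparse)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 ||
        (.finite && !is.finite(v))) {
      stop(sprintf("'%s' must be a single positive number (got %s)",
                   nms[i], deparse(v)), call. = FALSE)
    }
  }
  invisible(TRUE)
}
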
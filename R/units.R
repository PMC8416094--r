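#' Unit conversion constants and helpers
#'
#' All internal computation is in SI units (Pa, m^3/s, s). Clinical reporting
#' uses mmHg and ml/s; these helpers convert between the two conventions.
#' The mmHg conversion constant is fixed at 133.322 Pa/mmHg.
#'
#' @name units
NULL

#' @rdname units
#' @export
MMHG_TO_PA <- 133.322

#' @rdname units
#' @export
MLS_TO_M3S <- 1e-6

#' Convert mmHg to Pa
#' @param x pressure in mmHg
#' @return pressure in Pa
#' @export
mmHg_to_Pa <- function(x) x * MMHG_TO_PA

#' Convert Pa to mmHg
#' @param x pressure in Pa
#' @return pressure in mmHg
#' @export
Pa_to_mmHg <- function(x) x / MMHG_TO_PA

#' Convert ml/s to m^3/s
#' @param x flow in ml/s
#' @return flow in m^3/s
#' @export
mls_to_m3s <- function(x) x * MLS_TO_M3S

#' Convert m^3/s to ml/s
#' @param x flow in m^3/s
#' @return flow in ml/s
#' @export
m3s_to_mls <- function(x) x / MLS_TO_M3S

# internal: stop with a classed condition so callers can test on class
cf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cowflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
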
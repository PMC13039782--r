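#' Unit conversion constants and helpers
#'
#' All internal computation is in SI units; mmHg, mL and cm^2 appear only at
#' the I/O boundary. The conversion constant is fixed at 1 mmHg = 133.322 Pa.
#'
#' @name units
NULL

#' @rdname units
#' @export
MMHG_PA <- 133.322

#' Convert mmHg to Pa
#' @param x pressure in mmHg
#' @return pressure in Pa
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' Convert Pa to mmHg
#' @param x pressure in Pa
#' @return pressure in mmHg
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA
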
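# Unit conversions between the internal {Pa, mm^3, s} system and the
# reporting units {mmHg, mL, L/min}.

.PA_PER_MMHG <- 133.322
.MM3S_PER_LMIN <- 1e6 / 60  # 16666.67 mm^3/s per L/min

#' Unit conversion helpers
#'
#' Convert between internal SI-consistent units (Pa, mm^3, s) and the
#' clinical reporting units (mmHg, mL, L/min).
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / .PA_PER_MMHG

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * .PA_PER_MMHG

#' @rdname units
#' @export
mm3_to_ml <- function(x) x / 1000

#' @rdname units
#' @export
ml_to_mm3 <- function(x) x * 1000

#' @rdname units
#' @export
mm3s_to_lmin <- function(x) x / .MM3S_PER_LMIN

#' @rdname units
#' @export
lmin_to_mm3s <- function(x) x * .MM3S_PER_LMIN
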
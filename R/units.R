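#' Unit conversion constants
#'
#' All 0D interfaces use clinical units (mmHg, ml/s, ml/mmHg); the
#' quasi-1D solver works in SI (Pa, m^3/s, m^2). A single conversion
#' constant keeps the two faces consistent.
#'
#' @format `MMHG_TO_PA` is the number of pascal in one mmHg (133.322).
#' @export
MMHG_TO_PA <- 133.322

#' @rdname MMHG_TO_PA
#' @format `M3_PER_PA_TO_ML_PER_MMHG` converts a volume compliance from
#'   m^3/Pa to ml/mmHg.
#' @export
M3_PER_PA_TO_ML_PER_MMHG <- 1e6 * MMHG_TO_PA

# mmHg.s/ml -> Pa.s/m^3 and back (resistances, impedances)
MMHG_S_ML_TO_SI <- MMHG_TO_PA * 1e6

mmhg_to_pa <- function(p) p * MMHG_TO_PA
pa_to_mmhg <- function(p) p / MMHG_TO_PA

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite value in %s", what), call. = FALSE)
  invisible(x)
}
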
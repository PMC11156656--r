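# Matrix effect by calibration-slope comparison: negative values indicate
# ion suppression, positive values ion enhancement. |ME| <= 20% is "soft"
# (negligible; solvent-matched calibration permitted), beyond that
# "significant" (matrix-matched calibration required).

#' Matrix effect as a percentage of the solvent slope
#'
#' `100 * (slope_matrix - slope_solvent) / slope_solvent`.
#'
#' @param slope_matrix slope of the matrix-matched calibration curve.
#' @param slope_solvent slope of the solvent-based curve; must be non-zero.
#' @return matrix effect in percent (negative = suppression).
#' @examples
#' matrix_effect_percent(0.8, 1.0)  # -20
#' @export
matrix_effect_percent <- function(slope_matrix, slope_solvent) {
  if (any(slope_solvent == 0)) stop("solvent slope must be non-zero")
  100 * (slope_matrix - slope_solvent) / slope_solvent
}

#' Classify a matrix effect as soft or significant
#'
#' Soft (negligible) iff -20 <= ME <= 20, boundary inclusive; soft effects
#' permit solvent-matched calibration.
#'
#' @param me_percent matrix effect in percent; must be finite.
#' @return `"soft"` or `"significant"` (character, vectorized).
#' @export
classify_matrix_effect <- function(me_percent) {
  if (any(!is.finite(me_percent))) stop("matrix effect must be finite")
  ifelse(abs(me_percent) <= 20, "soft", "significant")
}

#' Matrix-effect assessment from two fitted calibration curves
#'
#' Consumes fitted curves rather than raw series so the fit policy
#' (weighting, medium bookkeeping) lives in [fit_calibration()] alone.
#'
#' @param curve_matrix matrix-matched [fit_calibration()] curve.
#' @param curve_solvent solvent-based curve.
#' @return an object of class `matrix_effect_result`: list with
#'   `me_percent`, `classification`, `slope_matrix`, `slope_solvent`.
#' @export
matrix_effect <- function(curve_matrix, curve_solvent) {
  stopifnot(inherits(curve_matrix, "calibration_curve"),
            inherits(curve_solvent, "calibration_curve"))
  me <- matrix_effect_percent(curve_matrix$slope, curve_solvent$slope)
  structure(
    list(me_percent = me, classification = classify_matrix_effect(me),
         slope_matrix = curve_matrix$slope, slope_solvent = curve_solvent$slope),
    class = "matrix_effect_result")
}

#' @export
print.matrix_effect_result <- function(x, ...) {
  cat(sprintf("Matrix effect: %+.2f%% (%s; slopes %g matrix vs %g solvent)\n",
              x$me_percent, x$classification, x$slope_matrix, x$slope_solvent))
  invisible(x)
}
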
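# Top-down expanded measurement uncertainty from intra-laboratory
# validation data: a bias component from recovery experiments, a precision
# component from the intermediate-precision RSD, combined in quadrature and
# expanded with a coverage factor (k = 2 ~ 95% coverage). Regulatory
# ceiling: 50%.
#
# Unit discipline: every internal uncertainty quantity is a fraction; only
# the expanded uncertainty is rendered in percent. The bias SD deliberately
# uses the population (n) denominator — it is the spread of the observed
# relative biases themselves, not an estimate of a wider population — while
# sample (n-1) SDs are used everywhere else in the package.

#' Mean and population SD of the relative bias
#'
#' Per-replicate relative bias is `(measured - true)/true`; returns its mean
#' and its population (n-denominator) SD.
#'
#' @param measured at least 2 measured values.
#' @param true_value the reference (spiked) value; > 0.
#' @return named numeric `c(mean_bias = ..., sdp_bias = ...)`, fractions.
#' @examples
#' relative_bias_stats(c(9, 10, 11), 10)  # mean 0, sdp sqrt(0.02/3)
#' @export
relative_bias_stats <- function(measured, true_value) {
  if (true_value <= 0) stop("true_value must be > 0")
  if (length(measured) < 2) stop("need at least 2 measurements")
  b <- (measured - true_value) / true_value
  n <- length(b)
  c(mean_bias = mean(b), sdp_bias = sqrt(sum((b - mean(b))^2) / n))
}

#' Standard uncertainty due to bias
#'
#' Euclidean combination of the mean relative bias and the population SD of
#' the relative bias: `sqrt(mean_bias^2 + sdp_bias^2)`.
#'
#' @param mean_bias,sdp_bias fractions; must be finite.
#' @return fraction.
#' @examples
#' u_bias(0.06, 0.08)  # 0.10
#' @export
u_bias <- function(mean_bias, sdp_bias) {
  if (!all(is.finite(c(mean_bias, sdp_bias)))) stop("inputs must be finite")
  sqrt(mean_bias^2 + sdp_bias^2)
}

#' Combined and expanded measurement uncertainty
#'
#' Combined standard uncertainty `u = sqrt(u_bias^2 + u_precision^2)`
#' (fractions), expanded uncertainty `U = 100 * k * u` (percent), compliance
#' against the 50% ceiling (inclusive).
#'
#' @param u_bias bias component, fraction (>= 0).
#' @param u_precision precision component, fraction (>= 0); conventionally
#'   the intermediate-precision (interday) RSD expressed as a fraction.
#' @param k coverage factor (default 2, approximately 95% coverage).
#' @return an object of class `uncertainty_result`: list with `u_bias`,
#'   `u_precision`, `u_combined` (fractions), `u_expanded_percent`,
#'   `coverage_factor`, `compliant`.
#' @examples
#' expanded_uncertainty(0.06, 0.08)  # U = 20%, compliant
#' @export
expanded_uncertainty <- function(u_bias, u_precision, k = 2) {
  if (u_bias < 0 || u_precision < 0 || k <= 0)
    stop("u_bias and u_precision must be >= 0 and k > 0")
  u <- sqrt(u_bias^2 + u_precision^2)
  U <- 100 * k * u
  structure(
    list(u_bias = u_bias, u_precision = u_precision, u_combined = u,
         u_expanded_percent = U, coverage_factor = k, compliant = U <= 50),
    class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf(
    "u(bias) = %.4f, u(precision) = %.4f -> u = %.4f; U(k=%g) = %.2f%% [%s]\n",
    x$u_bias, x$u_precision, x$u_combined, x$coverage_factor,
    x$u_expanded_percent, if (x$compliant) "compliant" else "NON-COMPLIANT"))
  invisible(x)
}

#' Measurement uncertainty from a spike-recovery experiment
#'
#' Convenience wrapper: bias statistics from the replicates against the
#' spike level, precision from the validation report's RSD (interday by
#' default, intraday pooled-within-day via `precision = "intraday"`),
#' combined and expanded with coverage factor `k`.
#'
#' @param spikes a [spike_set()].
#' @param k coverage factor.
#' @param precision which RSD feeds the precision component:
#'   `"interday"` (default) or `"intraday"`.
#' @return an `uncertainty_result` with added fields `mean_bias` and
#'   `sdp_bias`.
#' @export
uncertainty_from_spikes <- function(spikes, k = 2,
                                    precision = c("interday", "intraday")) {
  if (!inherits(spikes, "spike_set")) stop("spikes must be a spike_set")
  precision <- match.arg(precision)
  rep_ <- precision_report(spikes)
  bias <- relative_bias_stats(spikes$measured, attr(spikes, "spike_level"))
  u_prec <- switch(precision,
                   interday = rep_$rsd_interday,
                   intraday = rep_$rsd_intraday_pooled) / 100
  if (is.na(u_prec))
    stop("interday precision unavailable (single day); use precision = 'intraday'")
  out <- expanded_uncertainty(u_bias(bias["mean_bias"], bias["sdp_bias"]),
                              u_prec, k = k)
  out$mean_bias <- unname(bias["mean_bias"])
  out$sdp_bias <- unname(bias["sdp_bias"])
  out
}
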
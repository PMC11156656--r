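# SANTE-style method validation: recovery against the 60-140% window,
# repeatability (intraday RSD) and intermediate precision (interday RSD)
# against the <= 20% ceiling.

#' Construct a spike-recovery replicate set
#'
#' @param spike_level spiked concentration, ug/kg (> 0).
#' @param day day label per replicate (non-empty character).
#' @param measured measured concentration per replicate, ug/kg.
#' @return a data frame of class `spike_set` with a `spike_level` attribute.
#' @export
spike_set <- function(spike_level, day, measured) {
  if (spike_level <= 0) stop("spike_level must be > 0")
  day <- as.character(day)
  if (length(day) != length(measured)) stop("day and measured lengths differ")
  if (any(is.na(day) | !nzchar(day))) stop("day labels must be non-empty")
  out <- data.frame(day = day, measured = as.numeric(measured),
                    stringsAsFactors = FALSE)
  attr(out, "spike_level") <- spike_level
  class(out) <- c("spike_set", "data.frame")
  out
}

#' Recovery as a percentage of the spiked amount
#'
#' @param measured_mean mean measured concentration at the spike level.
#' @param spiked spiked concentration (> 0).
#' @return `100 * measured_mean / spiked`.
#' @examples
#' recovery_percent(8.8, 10)  # 88
#' @export
recovery_percent <- function(measured_mean, spiked) {
  if (any(spiked <= 0)) stop("spiked amount must be > 0")
  100 * measured_mean / spiked
}

#' Relative standard deviation in percent
#'
#' `100 * sd(values) / mean(values)`, with the sample (n - 1) SD.
#'
#' @param values at least 2 numeric values with non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd_percent(c(9, 10, 11))  # 10
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2) stop("RSD needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Validation report for a spike-recovery experiment
#'
#' Computes recovery from the grand mean of all replicates, repeatability as
#' the per-day (intraday) RSDs plus their pooled-within-day combination, and
#' intermediate precision as the RSD over all replicates pooled across days
#' (`interday = "pooled"`, the default, matching the usual
#' "n replicates over d days" reporting). `interday = "anova"` instead
#' reports the intermediate-precision RSD from a one-way random-effects
#' decomposition, sqrt(within + between variance components) / grand mean —
#' a diagnostic, not the headline figure.
#'
#' Pass flags follow the SANTE windows, boundaries inclusive: recovery in
#' [60, 140]% and every reported RSD <= 20%.
#'
#' @param spikes a [spike_set()].
#' @param interday `"pooled"` (default) or `"anova"`.
#' @return an object of class `validation_report`: list with
#'   `spike_level`, `recovery_percent`, `rsd_intraday` (named per-day),
#'   `rsd_intraday_pooled`, `rsd_interday`, `n_replicates`, `n_days`,
#'   `recovery_pass`, `precision_pass`.
#' @examples
#' s <- spike_set(10, rep(c("d1", "d2"), each = 3),
#'                c(9.6, 10.1, 9.9, 10.3, 9.8, 10.0))
#' precision_report(s)
#' @export
precision_report <- function(spikes, interday = c("pooled", "anova")) {
  if (!inherits(spikes, "spike_set")) stop("spikes must be a spike_set")
  interday <- match.arg(interday)
  level <- attr(spikes, "spike_level")
  days <- split(spikes$measured, spikes$day)
  if (any(vapply(days, length, 1L) < 2))
    stop("each day needs at least 2 replicates for an intraday RSD")
  grand <- mean(spikes$measured)
  rsd_by_day <- vapply(days, rsd_percent, numeric(1))
  within_var <- mean(vapply(days, stats::var, numeric(1)))
  pooled_within <- 100 * sqrt(within_var) / grand
  rsd_inter <- if (length(days) < 2) {
    NA_real_
  } else if (interday == "pooled") {
    rsd_percent(spikes$measured)
  } else {
    fit <- stats::aov(measured ~ day, data = spikes)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    n_per <- mean(vapply(days, length, 1L))
    between <- max(0, (ms[1] - ms[2]) / n_per)
    100 * sqrt(ms[2] + between) / grand
  }
  rec <- recovery_percent(grand, level)
  reported_rsd <- c(rsd_by_day, rsd_inter)
  structure(
    list(spike_level = level, recovery_percent = rec,
         rsd_intraday = rsd_by_day, rsd_intraday_pooled = pooled_within,
         rsd_interday = rsd_inter,
         n_replicates = nrow(spikes), n_days = length(days),
         recovery_pass = rec >= 60 && rec <= 140,
         precision_pass = all(reported_rsd[!is.na(reported_rsd)] <= 20)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Spike level %g ug/kg: recovery %.1f%% [%s]\n", x$spike_level,
              x$recovery_percent, if (x$recovery_pass) "pass" else "FAIL"))
  cat(sprintf("  intraday RSD: %s%%; interday RSD: %s%% [%s]\n",
              paste(sprintf("%.1f", x$rsd_intraday), collapse = ", "),
              ifelse(is.na(x$rsd_interday), "-", sprintf("%.1f", x$rsd_interday)),
              if (x$precision_pass) "pass" else "FAIL"))
  invisible(x)
}
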
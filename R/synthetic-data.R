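# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. Residues are lognormal with Bernoulli detection thinning and
# left-censoring at the LOD; calibration responses are linear with a
# multiplicative matrix-effect slope perturbation and additive Gaussian
# noise; blanks are Gaussian; spike replicates carry a configurable relative
# bias and relative SD.

#' Specification of a synthetic residue survey
#'
#' Describes, per pesticide, the lognormal concentration distribution
#' (matched by method of moments to an arithmetic mean and SD), the fraction
#' of samples in which the pesticide is detectable at all, and the
#' left-censoring limit (the method LOD).
#'
#' @param pesticides data frame with columns `name`, `target_mean`
#'   (arithmetic mean, ug/kg), `target_sd` (arithmetic SD, ug/kg),
#'   `detection_frequency` (fraction in `[0, 1]`), `censor_limit`
#'   (LOD, ug/kg).
#' @param n_samples number of survey samples (rows per pesticide).
#' @param seed master seed for the residue substreams.
#' @return an object of class `residue_sim_spec`.
#' @seealso [generate_residue_table()], [study_fixture()]
#' @export
residue_sim_spec <- function(pesticides, n_samples, seed) {
  stopifnot(is.data.frame(pesticides), nrow(pesticides) >= 1)
  need <- c("name", "target_mean", "target_sd", "detection_frequency", "censor_limit")
  miss <- setdiff(need, names(pesticides))
  if (length(miss))
    stop("pesticides is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pesticides$name))
    stop("duplicated pesticide names in spec")
  if (any(pesticides$target_mean <= 0)) stop("target_mean must be > 0")
  if (any(pesticides$target_sd < 0)) stop("target_sd must be >= 0")
  if (any(pesticides$detection_frequency < 0 | pesticides$detection_frequency > 1))
    stop("detection_frequency must lie in [0, 1]")
  if (any(pesticides$censor_limit < 0)) stop("censor_limit must be >= 0")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be a single integer >= 1")
  structure(
    list(pesticides = pesticides[need], n_samples = as.integer(n_samples),
         seed = seed),
    class = "residue_sim_spec")
}

#' Specification of a synthetic calibration experiment
#'
#' @param true_slope true relative-response slope (per ug/kg).
#' @param true_intercept true intercept (relative-response units).
#' @param noise_sd SD of additive Gaussian noise on the relative response.
#' @param levels calibration concentrations, ug/kg; strictly positive and
#'   strictly increasing. Defaults to the 12-level series
#'   0.001--500 ug/kg used throughout the package.
#' @param matrix_effect_factor multiplicative slope perturbation applied in
#'   matrix medium (e.g. 0.8 for 20% ion suppression).
#' @param seed master seed.
#' @return an object of class `calibration_sim_spec`.
#' @export
calibration_sim_spec <- function(true_slope, true_intercept = 0, noise_sd = 0,
                                 levels = default_calibration_levels(),
                                 matrix_effect_factor = 1, seed = 1L) {
  stopifnot(length(levels) >= 1)
  if (any(levels <= 0)) stop("levels must be strictly positive")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(true_slope = true_slope, true_intercept = true_intercept,
         noise_sd = noise_sd, levels = as.numeric(levels),
         matrix_effect_factor = matrix_effect_factor, seed = seed),
    class = "calibration_sim_spec")
}

#' Default calibration levels (ug/kg)
#'
#' The 12-point series spanning five decades used for all calibration
#' simulations: 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50, 100, 500.
#'
#' @return numeric vector of length 12.
#' @export
default_calibration_levels <- function() {
  c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1.0, 5.0, 10, 50, 100, 500)
}

#' Generate a per-sample residue table
#'
#' For each pesticide, each of `n_samples` samples is first thinned by an
#' independent Bernoulli draw with the spec's `detection_frequency`;
#' detectable samples receive a concentration drawn from the lognormal whose
#' arithmetic mean and SD match the spec targets (method of moments).
#' Censoring at `censor_limit` is handled either by marking sub-limit draws
#' as non-detects (`"censor"`, the default: detection frequencies in real
#' surveys arise from censoring) or by redrawing until the value clears the
#' limit (`"truncate"`).
#'
#' @param spec a [residue_sim_spec()].
#' @param censoring `"censor"` or `"truncate"`.
#' @return a data frame of class `residue_table` with columns `sample_id`,
#'   `pesticide`, `concentration_ug_per_kg` (NA for non-detects), `detected`
#'   (integer 0/1).
#' @examples
#' spec <- residue_sim_spec(
#'   data.frame(name = "carbosulfan", target_mean = 10.33, target_sd = 5.5,
#'              detection_frequency = 1, censor_limit = 0.0107),
#'   n_samples = 10, seed = 1)
#' generate_residue_table(spec)
#' @export
generate_residue_table <- function(spec, censoring = c("censor", "truncate")) {
  if (!inherits(spec, "residue_sim_spec")) stop("spec must be a residue_sim_spec")
  censoring <- match.arg(censoring)
  n <- spec$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  rows <- lapply(seq_len(nrow(spec$pesticides)), function(i) {
    p <- spec$pesticides[i, ]
    lp <- fit_lognormal_moments(p$target_mean, p$target_sd)
    with_substream(spec$seed, paste0("residues:", p$name), {
      detected <- stats::runif(n) < p$detection_frequency
      conc <- rep(NA_real_, n)
      k <- sum(detected)
      if (k > 0) {
        draw <- stats::rlnorm(k, lp["mu"], lp["sigma"])
        if (censoring == "truncate") {
          bad <- which(draw < p$censor_limit)
          guard <- 0L
          while (length(bad) > 0 && guard < 10000L) {
            draw[bad] <- stats::rlnorm(length(bad), lp["mu"], lp["sigma"])
            bad <- which(draw < p$censor_limit)
            guard <- guard + 1L
          }
          if (length(bad) > 0)
            stop("censor_limit too high relative to the target distribution")
          conc[detected] <- draw
        } else {
          below <- draw < p$censor_limit
          conc[detected] <- ifelse(below, NA_real_, draw)
          detected[detected] <- !below
        }
      }
      data.frame(sample_id = ids, pesticide = p$name,
                 concentration_ug_per_kg = conc,
                 detected = as.integer(detected),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("residue_table", "data.frame")
  out
}

#' Generate a synthetic internal-standard calibration series
#'
#' One point per level. The expected relative response is
#' `slope_eff * conc + intercept` with `slope_eff = true_slope *
#' matrix_effect_factor` in matrix medium and `true_slope` in solvent;
#' Gaussian noise with SD `noise_sd` is added to the relative response. The
#' internal-standard area is held at a fixed nominal value and the analyte
#' area back-computed, so `analyte_area / is_area` carries the response.
#'
#' @param spec a [calibration_sim_spec()].
#' @param medium `"solvent"` or `"matrix"`.
#' @param is_area nominal internal-standard peak area.
#' @return a [calibration_series()].
#' @export
generate_calibration_series <- function(spec, medium = c("solvent", "matrix"),
                                        is_area = 1e5) {
  if (!inherits(spec, "calibration_sim_spec")) stop("spec must be a calibration_sim_spec")
  medium <- match.arg(medium)
  slope <- spec$true_slope * if (medium == "matrix") spec$matrix_effect_factor else 1
  rr <- with_substream(spec$seed, paste0("calibration:", medium), {
    slope * spec$levels + spec$true_intercept +
      stats::rnorm(length(spec$levels), 0, spec$noise_sd)
  })
  calibration_series(
    nominal_concentration = spec$levels,
    analyte_area = rr * is_area,
    is_area = rep(is_area, length(spec$levels)),
    medium = medium)
}

#' Generate replicate blank-signal measurements
#'
#' Gaussian blank signals, by default the 20-measurement design used to
#' estimate the mean blank signal and its SD for LOD/LOQ work.
#'
#' @param mean,sd mean and SD of the blank signal (response units; `sd >= 0`).
#' @param n number of blank measurements (default 20).
#' @param seed master seed.
#' @return a [blank_set()].
#' @export
generate_blank_signals <- function(mean, sd, n = 20, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("need at least 2 blank measurements")
  signals <- with_substream(seed, "blanks", stats::rnorm(n, mean, sd))
  blank_set(signals)
}

#' Generate spike-recovery replicates over one or more days
#'
#' Measured concentrations have expectation `spike_level * (1 + bias_frac)`
#' and coefficient of variation approximately `rsd_frac`, labeled by day.
#' The default design (6 replicates per day over 2 days) mirrors the common
#' intraday/interday validation layout.
#'
#' @param spike_level spiked concentration, ug/kg (> 0).
#' @param bias_frac relative bias of the measurement (e.g. -0.12 for a
#'   method that recovers 88%).
#' @param rsd_frac relative SD of the measurement (fraction, >= 0).
#' @param n_per_day replicates per day (>= 1).
#' @param n_days number of days (>= 1).
#' @param seed master seed.
#' @return a [spike_set()].
#' @export
generate_spike_replicates <- function(spike_level, bias_frac = 0, rsd_frac = 0,
                                      n_per_day = 6, n_days = 2, seed = 1L) {
  if (spike_level <= 0) stop("spike_level must be > 0")
  if (rsd_frac < 0) stop("rsd_frac must be >= 0")
  if (n_per_day < 1 || n_days < 1) stop("n_per_day and n_days must be >= 1")
  mu <- spike_level * (1 + bias_frac)
  reps <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    m <- with_substream(seed, paste0("spikes:day", d),
                        stats::rnorm(n_per_day, mu, abs(mu) * rsd_frac))
    data.frame(day = paste0("day", d), replicate = seq_len(n_per_day),
               measured = m, stringsAsFactors = FALSE)
  }))
  spike_set(spike_level = spike_level, day = reps$day,
            measured = reps$measured)
}

# Table of the bundled 14-pesticide survey scenario: detection counts out of
# 55 samples, observed concentration range and mean (ug/kg), the printed
# dispersion of the mean, the method LOD used as censor limit, and the
# regulatory MRL.
study_scenario_table <- function() {
  data.frame(
    name = c("carbosulfan", "phenmedipham", "carbaryl", "propoxur",
             "propamocarb", "aminocarb", "ethiofencarb", "pirimicarb",
             "bendiocarb", "fenoxycarb", "carbofuran", "methomyl",
             "desmedipham", "methiocarb"),
    n_detected = c(55L, 46L, 14L, 53L, 43L, 52L, 51L, 27L, 22L, 31L, 33L,
                   15L, 3L, 8L),
    min = c(2.54, 0.10, 0.04, 0.73, 0.28, 0.06, 0.34, 0.19, 0.06, 0.03,
            0.13, 0.22, 0.58, 0.03),
    max = c(24.77, 4.23, 1.65, 6.08, 1.21, 3.28, 3.53, 3.93, 1.85, 5.93,
            3.27, 1.70, 4.43, 1.24),
    mean = c(10.33, 0.63, 0.46, 1.48, 0.51, 0.60, 1.28, 0.99, 0.49, 1.49,
             0.85, 0.86, 2.93, 0.39),
    printed_dispersion = c(0.19, 0.03, 0.02, 0.06, 0.02, 0.02, 0.06, 0.04,
                           0.02, 0.04, 0.03, 0.02, 0.13, 0.02),
    lod = c(0.0107, 0.0015, 0.0014, 0.0011, 0.0049, 0.0010, 0.0011, 0.0053,
            0.0014, 0.0011, 0.0011, 0.0131, 0.0014, 0.0013),
    mrl = c(10, 10, 10, 5, 10, 10, 10, 10, 10, 10, 3, 10, 10, 30),
    stringsAsFactors = FALSE)
}

#' Bundled study fixture: a 55-sample date-fruit carbamate survey
#'
#' Returns everything needed to run the full pipeline on a synthetic
#' re-creation of a 14-carbamate monitoring campaign over 55 date samples:
#' a [residue_sim_spec()] parameterized from the campaign's summary
#' statistics, the MRL table (ug/kg), the chronic oral reference doses
#' (RfDo, mg/kg/day; available for six of the fourteen pesticides), and the
#' adult and child consumer exposure profiles.
#'
#' The published summary reports, per pesticide, a mean, a "+/-" dispersion
#' and an observed range. The printed dispersions are far too small to be
#' sample SDs given the ranges (they are plausibly standard errors), so two
#' interpretations are offered for the lognormal target SD:
#' `"range"` (default) takes SD = (max - min)/4, the usual range heuristic,
#' which is consistent with the reported hazard-index scale;
#' `"printed"` takes the printed dispersion literally as the SD.
#'
#' @param dispersion `"range"` or `"printed"`; how the per-pesticide target
#'   SD is derived (see Details).
#' @param n_samples number of synthetic survey samples (default 55).
#' @param seed master seed for the residue substreams.
#' @return a list with elements `residue_spec` ([residue_sim_spec()]),
#'   `mrl_table` (named numeric, ug/kg), `rfdo_table` (named numeric,
#'   mg/kg/day), `profiles` (list of two [exposure_profile()]s), and
#'   `scenario` (the underlying summary data frame).
#' @examples
#' fx <- study_fixture(seed = 1)
#' fx$mrl_table[["carbofuran"]]
#' fx$profiles$adult
#' @export
study_fixture <- function(dispersion = c("range", "printed"), n_samples = 55,
                          seed = 20240606) {
  dispersion <- match.arg(dispersion)
  tab <- study_scenario_table()
  sd <- switch(dispersion,
               range = (tab$max - tab$min) / 4,
               printed = tab$printed_dispersion)
  spec <- residue_sim_spec(
    data.frame(name = tab$name, target_mean = tab$mean, target_sd = sd,
               detection_frequency = tab$n_detected / 55,
               censor_limit = tab$lod, stringsAsFactors = FALSE),
    n_samples = n_samples, seed = seed)
  rfdo <- c(carbosulfan = 0.01, phenmedipham = 0.25, carbaryl = 0.1,
            propoxur = 0.005, carbofuran = 0.005, methomyl = 0.25)
  list(
    residue_spec = spec,
    mrl_table = stats::setNames(tab$mrl, tab$name),
    rfdo_table = rfdo,
    profiles = list(
      adult = exposure_profile("adult", ingestion_rate_g_day = 114.3,
                               body_weight_kg = 70),
      child = exposure_profile("child", ingestion_rate_g_day = 35,
                               body_weight_kg = 15)),
    scenario = tab)
}
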
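# Probabilistic non-carcinogenic dietary risk assessment. Per pesticide a
# lognormal concentration model (method-of-moments fit to the arithmetic
# mean and SD of the residues) feeds a Monte-Carlo chain
#   concentration (ug/kg -> mg/kg) -> CDI = C * IR / BW -> HQ = CDI / RfDo,
# and the hazard index is the sum over pesticides of the 95th-percentile
# HQs. HI < 1 is read as no non-carcinogenic risk.
#
# Unit discipline: residue concentrations live in ug/kg and are converted
# to mg/kg inside cdi(); ingestion rates are held in g/day and converted to
# kg/day inside cdi(). These are the only unit conversions in the chain.

#' Consumer exposure profile
#'
#' @param label profile name, e.g. `"adult"`.
#' @param ingestion_rate_g_day daily commodity intake, g/day (> 0).
#' @param body_weight_kg body weight, kg (> 0).
#' @return an object of class `exposure_profile`.
#' @examples
#' exposure_profile("adult", 114.3, 70)
#' @export
exposure_profile <- function(label, ingestion_rate_g_day, body_weight_kg) {
  if (ingestion_rate_g_day <= 0 || body_weight_kg <= 0)
    stop("ingestion rate and body weight must be > 0")
  structure(list(label = label, ingestion_rate_g_day = ingestion_rate_g_day,
                 body_weight_kg = body_weight_kg),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("Exposure profile '%s': IR = %g g/day, BW = %g kg\n",
              x$label, x$ingestion_rate_g_day, x$body_weight_kg))
  invisible(x)
}

#' Fit a lognormal by matching arithmetic mean and SD
#'
#' Method of moments: `mu = ln(m^2 / sqrt(m^2 + s^2))`,
#' `sigma = sqrt(ln(1 + s^2/m^2))`, so that `exp(mu + sigma^2/2) = m` and
#' the lognormal variance equals `s^2`. `s = 0` gives the degenerate point
#' mass (`sigma = 0`).
#'
#' @param arith_mean arithmetic mean (> 0).
#' @param arith_sd arithmetic SD (>= 0).
#' @return named numeric `c(mu = ..., sigma = ...)` (log-space).
#' @examples
#' fit_lognormal_moments(10.33, 5.5)
#' @export
fit_lognormal_moments <- function(arith_mean, arith_sd) {
  if (arith_mean <= 0) stop("arith_mean must be > 0")
  if (arith_sd < 0) stop("arith_sd must be >= 0")
  cv2 <- (arith_sd / arith_mean)^2
  c(mu = log(arith_mean / sqrt(1 + cv2)), sigma = sqrt(log(1 + cv2)))
}

#' Lognormal concentration model for one pesticide
#'
#' @param pesticide pesticide name.
#' @param arith_mean,arith_sd arithmetic moments of the residue
#'   concentration, ug/kg.
#' @return an object of class `lognormal_concentration_model` with fields
#'   `pesticide`, `arith_mean`, `arith_sd`, `mu`, `sigma`.
#' @export
lognormal_concentration_model <- function(pesticide, arith_mean, arith_sd) {
  p <- fit_lognormal_moments(arith_mean, arith_sd)
  structure(list(pesticide = pesticide, arith_mean = arith_mean,
                 arith_sd = arith_sd, mu = unname(p["mu"]),
                 sigma = unname(p["sigma"])),
            class = "lognormal_concentration_model")
}

#' Chronic daily intake
#'
#' `CDI = C * IR / BW` with the concentration in mg/kg: the `concentration`
#' argument is in ug/kg (the native unit of the residue tables) and is
#' converted here, as is the ingestion rate from g/day to kg/day.
#'
#' @param concentration_ug_per_kg residue concentration, ug/kg (>= 0).
#' @param profile an [exposure_profile()].
#' @return CDI in mg/kg body weight/day. Vectorized over concentration.
#' @examples
#' adult <- exposure_profile("adult", 114.3, 70)
#' cdi(10.33, adult)  # 1.6867e-5 mg/kg/day
#' @export
cdi <- function(concentration_ug_per_kg, profile) {
  stopifnot(inherits(profile, "exposure_profile"))
  if (any(concentration_ug_per_kg < 0)) stop("concentration must be >= 0")
  conc_mg_per_kg <- concentration_ug_per_kg / 1000
  ir_kg_day <- profile$ingestion_rate_g_day / 1000
  conc_mg_per_kg * ir_kg_day / profile$body_weight_kg
}

#' Hazard quotient
#'
#' `HQ = CDI / RfDo`; HQ < 1 is read as no non-carcinogenic risk.
#'
#' @param cdi_value chronic daily intake, mg/kg/day.
#' @param rfdo chronic oral reference dose, mg/kg/day (> 0).
#' @return dimensionless ratio. Vectorized.
#' @export
hazard_quotient <- function(cdi_value, rfdo) {
  if (any(rfdo <= 0)) stop("RfDo must be > 0")
  cdi_value / rfdo
}

#' Monte-Carlo hazard-quotient simulation for one pesticide
#'
#' Draws `n_replicates` concentrations from the lognormal model, maps each
#' through [cdi()] and [hazard_quotient()], and summarizes the HQ sample by
#' its mean and empirical 95th percentile (linear interpolation between
#' order statistics, [stats::quantile()] type 7 — stated so results are
#' reproducible bit-for-bit given a seed).
#'
#' @param model a [lognormal_concentration_model()].
#' @param profile an [exposure_profile()].
#' @param rfdo reference dose, mg/kg/day.
#' @param n_replicates number of Monte-Carlo draws (default 100000).
#' @param seed substream seed passed to [set.seed()].
#' @param keep_draws if TRUE the HQ draws are returned (for plotting).
#' @return list with `pesticide`, `hq_mean`, `hq_p95`, `n_replicates`,
#'   `seed`, and optionally `draws`.
#' @export
simulate_hq <- function(model, profile, rfdo, n_replicates = 100000, seed = 1L,
                        keep_draws = FALSE) {
  stopifnot(inherits(model, "lognormal_concentration_model"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  conc <- with_substream(seed, paste0("hq:", model$pesticide),
                         stats::rlnorm(n_replicates, model$mu, model$sigma))
  hq <- hazard_quotient(cdi(conc, profile), rfdo)
  out <- list(pesticide = model$pesticide, hq_mean = mean(hq),
              hq_p95 = unname(stats::quantile(hq, 0.95, type = 7)),
              n_replicates = as.integer(n_replicates), seed = seed)
  if (keep_draws) out$draws <- hq
  out
}

#' Closed-form 95th-percentile hazard quotient
#'
#' Analytic counterpart of [simulate_hq()]: a lognormal scaled by a positive
#' constant is lognormal, so the HQ p95 is
#' `exp(mu + z_0.95 * sigma) * 1e-3 * (IR kg/day) / BW / RfDo` with
#' `z_0.95 = qnorm(0.95)`. Used as the independent oracle for the
#' Monte-Carlo machinery.
#'
#' @inheritParams simulate_hq
#' @return dimensionless HQ 95th percentile.
#' @export
hq_p95_closed_form <- function(model, profile, rfdo) {
  stopifnot(inherits(model, "lognormal_concentration_model"))
  conc_p95 <- exp(model$mu + stats::qnorm(0.95) * model$sigma)
  hazard_quotient(cdi(conc_p95, profile), rfdo)
}

#' Hazard index
#'
#' Arithmetic sum of per-pesticide 95th-percentile hazard quotients.
#' HI < 1 is read as no non-carcinogenic risk.
#'
#' @param per_pesticide_p95 numeric vector of per-pesticide HQ p95 values,
#'   all >= 0.
#' @return the sum; 0 (with a warning) for an empty input.
#' @export
hazard_index <- function(per_pesticide_p95) {
  if (length(per_pesticide_p95) == 0) {
    warning("no pesticides contributed to the hazard index")
    return(0)
  }
  if (any(per_pesticide_p95 < 0)) stop("HQ percentiles must be >= 0")
  sum(per_pesticide_p95)
}

#' Full Monte-Carlo risk assessment for one consumer profile
#'
#' Runs [simulate_hq()] for every model with an available reference dose and
#' sums the 95th-percentile HQs into the hazard index. Pesticides lacking an
#' RfDo are excluded with a message (risk cannot be quantified for them).
#' Each pesticide draws from its own named substream of `seed`, so the same
#' seed gives common random numbers across profiles: HQ draws for two
#' profiles differ only by the constant factor (IR/BW ratio).
#'
#' @param models list of [lognormal_concentration_model()]s.
#' @param rfdo_table named numeric vector, pesticide -> RfDo (mg/kg/day).
#' @param profile an [exposure_profile()].
#' @param n_replicates Monte-Carlo draws per pesticide.
#' @param seed master seed.
#' @param diagnostics if TRUE, additionally reports `hi_sum_p95`, the 95th
#'   percentile of the per-replicate HQ *sum* (a stricter aggregate than the
#'   sum of per-pesticide percentiles; diagnostic only, not the headline HI).
#' @return an object of class `risk_result`: list with `profile`,
#'   `per_pesticide` (data frame: pesticide, hq_mean, hq_p95), `hi`,
#'   `excluded` (pesticides without RfDo), `n_replicates`, `seed`, and
#'   optionally `hi_sum_p95`.
#' @examples
#' m <- list(lognormal_concentration_model("carbosulfan", 10.33, 5.5))
#' adult <- exposure_profile("adult", 114.3, 70)
#' assess_risk(m, c(carbosulfan = 0.01), adult, n_replicates = 1000, seed = 1)
#' @export
assess_risk <- function(models, rfdo_table, profile, n_replicates = 100000,
                        seed = 1L, diagnostics = FALSE) {
  stopifnot(inherits(profile, "exposure_profile"))
  names_ <- vapply(models, function(m) m$pesticide, character(1))
  has_rfdo <- names_ %in% names(rfdo_table)
  if (any(!has_rfdo))
    message("excluded from HI (no RfDo available): ",
            paste(names_[!has_rfdo], collapse = ", "))
  kept <- models[has_rfdo]
  sims <- lapply(kept, function(m)
    simulate_hq(m, profile, rfdo_table[[m$pesticide]],
                n_replicates = n_replicates, seed = seed,
                keep_draws = diagnostics))
  per <- data.frame(
    pesticide = vapply(sims, `[[`, character(1), "pesticide"),
    hq_mean = vapply(sims, `[[`, numeric(1), "hq_mean"),
    hq_p95 = vapply(sims, `[[`, numeric(1), "hq_p95"),
    stringsAsFactors = FALSE)
  out <- list(profile = profile, per_pesticide = per,
              hi = hazard_index(per$hq_p95),
              excluded = names_[!has_rfdo],
              n_replicates = as.integer(n_replicates), seed = seed)
  if (diagnostics && length(sims) > 0) {
    total <- Reduce(`+`, lapply(sims, `[[`, "draws"))
    out$hi_sum_p95 <- unname(stats::quantile(total, 0.95, type = 7))
  }
  class(out) <- "risk_result"
  out
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Risk assessment, profile '%s' (n = %d replicates, seed %s)\n",
              x$profile$label, x$n_replicates, format(x$seed)))
  for (i in seq_len(nrow(x$per_pesticide)))
    cat(sprintf("  %-14s HQ mean %.3e  HQ p95 %.3e\n",
                x$per_pesticide$pesticide[i], x$per_pesticide$hq_mean[i],
                x$per_pesticide$hq_p95[i]))
  cat(sprintf("  HI = %.3e -> %s\n", x$hi,
              if (x$hi < 1) "no non-carcinogenic risk" else "potential risk"))
  if (length(x$excluded))
    cat("  excluded (no RfDo): ", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Concentration models from a survey summary table
#'
#' Builds one [lognormal_concentration_model()] per pesticide from a
#' [build_summary_table()] result (using the detect-only mean and SD) or
#' from a residue-spec data frame with `target_mean`/`target_sd` columns.
#'
#' @param summary_table a `residue_summary_table`, or any data frame with
#'   columns `pesticide` (or `name`), `mean` (or `target_mean`) and `sd`
#'   (or `target_sd`).
#' @param pesticides optional subset of pesticide names.
#' @return list of models.
#' @export
concentration_models <- function(summary_table, pesticides = NULL) {
  df <- as.data.frame(summary_table)
  name <- if ("pesticide" %in% names(df)) df$pesticide else df$name
  m <- if ("mean" %in% names(df)) df$mean else df$target_mean
  s <- if ("sd" %in% names(df)) df$sd else df$target_sd
  if (is.null(name) || is.null(m) || is.null(s))
    stop("summary_table must provide pesticide names, means and SDs")
  keep <- if (is.null(pesticides)) seq_along(name) else match(pesticides, name)
  if (anyNA(keep)) stop("pesticide(s) not found in summary table")
  lapply(keep, function(i) lognormal_concentration_model(name[i], m[i], s[i]))
}

#' Histogram of a Monte-Carlo HQ sample
#'
#' Simple base-graphics histogram of the HQ draws with the mean and the
#' 95th percentile marked.
#'
#' @param hq_sim a [simulate_hq()] result with `keep_draws = TRUE`.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plot_hq_distribution <- function(hq_sim, ...) {
  if (is.null(hq_sim$draws))
    stop("simulate_hq() must be run with keep_draws = TRUE to plot")
  h <- graphics::hist(hq_sim$draws, breaks = 60,
                      main = paste("HQ distribution:", hq_sim$pesticide),
                      xlab = "Hazard quotient", ...)
  graphics::abline(v = hq_sim$hq_mean, lty = 2)
  graphics::abline(v = hq_sim$hq_p95, lty = 3)
  invisible(h)
}
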
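# Builders shared across test files. All synthetic, built in code.

# noiseless calibration series on a known line
noiseless_series <- function(slope, intercept = 0,
                             levels = default_calibration_levels(),
                             medium = "solvent", is_area = 100) {
  rr <- slope * levels + intercept
  calibration_series(levels, analyte_area = rr * is_area,
                     is_area = rep(is_area, length(levels)), medium = medium)
}

# residue table with given detected concentrations plus non-detect padding
make_residue_table <- function(pesticide, detects, n_total) {
  stopifnot(length(detects) <= n_total)
  n_nd <- n_total - length(detects)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n_total)),
    pesticide = pesticide,
    concentration_ug_per_kg = c(detects, rep(NA_real_, n_nd)),
    detected = c(rep(1L, length(detects)), rep(0L, n_nd)),
    stringsAsFactors = FALSE)
}

# single-pesticide simulation spec with permissive defaults
one_pesticide_spec <- function(mean = 10.33, sd = 5.5, freq = 1,
                               lod = 0.0107, n = 100, seed = 42,
                               name = "carbosulfan") {
  residue_sim_spec(
    data.frame(name = name, target_mean = mean, target_sd = sd,
               detection_frequency = freq, censor_limit = lod,
               stringsAsFactors = FALSE),
    n_samples = n, seed = seed)
}
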
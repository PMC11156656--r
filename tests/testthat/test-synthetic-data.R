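test_that("residue generation is deterministic under a fixed seed and honors boundaries", {
  spec <- one_pesticide_spec(freq = 1, n = 200, seed = 7)
  a <- generate_residue_table(spec)
  b <- generate_residue_table(spec)
  expect_identical(a, b)
  # full detection frequency with a tiny LOD: everything detected
  expect_true(all(a$detected == 1L))
  expect_true(all(a$concentration_ug_per_kg > 0))
  # different seed changes the draws
  spec2 <- one_pesticide_spec(freq = 1, n = 200, seed = 8)
  expect_false(identical(generate_residue_table(spec2)$concentration_ug_per_kg,
                         a$concentration_ug_per_kg))
  # zero detection frequency: nothing detected, concentrations absent
  spec0 <- one_pesticide_spec(freq = 0, n = 50)
  z <- generate_residue_table(spec0)
  expect_true(all(z$detected == 0L))
  expect_true(all(is.na(z$concentration_ug_per_kg)))
})

test_that("detection thinning tracks the requested frequency and censoring modes differ as designed", {
  spec <- one_pesticide_spec(mean = 1, sd = 1, freq = 0.6, lod = 0.05,
                             n = 20000, seed = 11)
  cen <- generate_residue_table(spec, censoring = "censor")
  # censored draws can only lower the detection rate below the Bernoulli rate
  p_cen <- mean(cen$detected)
  expect_lt(abs(p_cen - 0.6), 0.02)  # LOD cuts only ~0.4% of this lognormal
  tru <- generate_residue_table(spec, censoring = "truncate")
  det <- tru$concentration_ug_per_kg[tru$detected == 1]
  expect_true(all(det >= 0.05))  # truncate mode never emits sub-LOD detects
})

test_that("large-sample residue moments match the simulation targets", {
  spec <- one_pesticide_spec(mean = 10.33, sd = 5.5, freq = 1, lod = 0.0107,
                             n = 50000, seed = 123)
  rt <- generate_residue_table(spec)
  x <- rt$concentration_ug_per_kg[rt$detected == 1]
  expect_lt(abs(mean(x) - 10.33) / 10.33, 0.02)
  expect_lt(abs(sd(x) - 5.5) / 5.5, 0.02)
})

test_that("residue spec validation rejects bad parameters", {
  base <- data.frame(name = "x", target_mean = 1, target_sd = 1,
                     detection_frequency = 0.5, censor_limit = 0.01)
  expect_error(residue_sim_spec(transform(base, target_mean = 0), 10, 1),
               "target_mean")
  expect_error(residue_sim_spec(transform(base, target_sd = -1), 10, 1),
               "target_sd")
  expect_error(residue_sim_spec(transform(base, detection_frequency = 1.2), 10, 1),
               "detection_frequency")
  expect_error(residue_sim_spec(base, 0, 1), "n_samples")
  expect_error(residue_sim_spec(base[, -1], 10, 1), "missing column")
})

test_that("calibration simulation hits the true line when noiseless and perturbs the slope in matrix", {
  spec <- calibration_sim_spec(true_slope = 0.6, true_intercept = 0.01,
                               noise_sd = 0, matrix_effect_factor = 0.8,
                               seed = 5)
  solv <- generate_calibration_series(spec, "solvent")
  expect_equal(fit_calibration(solv)$slope, 0.6, tolerance = 1e-12)
  expect_equal(fit_calibration(solv)$intercept, 0.01, tolerance = 1e-12)
  matr <- generate_calibration_series(spec, "matrix")
  expect_equal(fit_calibration(matr)$slope, 0.6 * 0.8, tolerance = 1e-12)
  # reproducibility with noise
  spec_n <- calibration_sim_spec(0.6, 0.01, noise_sd = 0.01, seed = 5)
  expect_identical(generate_calibration_series(spec_n, "solvent"),
                   generate_calibration_series(spec_n, "solvent"))
  expect_error(calibration_sim_spec(0.6, levels = c(1, 1, 2)), "increasing")
  expect_error(calibration_sim_spec(0.6, levels = numeric(0)))
})

test_that("blank generation: default n, degenerate SD, and sampling fidelity", {
  b0 <- generate_blank_signals(0.5, 0, seed = 1)
  expect_length(b0$signals, 20)              # default replicate count
  expect_true(all(b0$signals == 0.5))
  expect_identical(b0$sd_blank, 0)
  big <- generate_blank_signals(0.5, 0.1, n = 10000, seed = 2)
  expect_lt(abs(big$sd_blank - 0.1) / 0.1, 0.03)
  expect_error(generate_blank_signals(0.5, -1), "sd")
  expect_error(generate_blank_signals(0.5, 0.1, n = 1), "at least 2")
})

test_that("spike replicates carry the configured bias and spread", {
  exact <- generate_spike_replicates(10, bias_frac = 0, rsd_frac = 0, seed = 1)
  expect_true(all(exact$measured == 10))
  expect_equal(nrow(exact), 12)              # 6 per day x 2 days
  expect_equal(sort(unique(exact$day)), c("day1", "day2"))
  biased <- generate_spike_replicates(10, bias_frac = -0.12, rsd_frac = 0.05,
                                      n_per_day = 500, n_days = 2, seed = 3)
  rec <- recovery_percent(mean(biased$measured), 10)
  expect_lt(abs(rec - 88), 0.5)
  expect_error(generate_spike_replicates(0), "spike_level")
})

test_that("study fixture carries the survey constants and both dispersion modes", {
  fx <- study_fixture(seed = 1)
  expect_equal(nrow(fx$residue_spec$pesticides), 14)
  expect_equal(fx$mrl_table[["carbofuran"]], 3)
  expect_equal(fx$mrl_table[["propoxur"]], 5)
  expect_equal(fx$mrl_table[["methiocarb"]], 30)
  expect_equal(fx$rfdo_table[["propoxur"]], 0.005)
  expect_equal(fx$profiles$adult$ingestion_rate_g_day, 114.3)
  expect_equal(fx$profiles$adult$body_weight_kg, 70)
  expect_equal(fx$profiles$child$ingestion_rate_g_day, 35)
  expect_equal(fx$profiles$child$body_weight_kg, 15)
  # dispersion modes give range/4 vs the printed dispersion for carbosulfan
  sd_range <- study_fixture(dispersion = "range")$residue_spec$pesticides$target_sd[1]
  sd_printed <- study_fixture(dispersion = "printed")$residue_spec$pesticides$target_sd[1]
  expect_equal(sd_range, (24.77 - 2.54) / 4)
  expect_equal(sd_printed, 0.19)
})

test_that("substream seeds separate streams and stay in integer range", {
  s1 <- substream_seed(1, "a")
  expect_identical(s1, substream_seed(1, "a"))
  expect_false(s1 == substream_seed(1, "b"))
  expect_false(s1 == substream_seed(2, "a"))
  big <- substream_seed(2^31 - 1, paste(rep("x", 100), collapse = ""))
  expect_true(big >= 0 && big < 2^31)
  expect_true(is.integer(big))
})
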
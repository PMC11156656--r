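test_that("relative response is the area ratio and rejects a missing IS", {
  expect_equal(relative_response(100, 100), 1.0)
  expect_equal(relative_response(250, 100), 2.5)
  expect_equal(relative_response(c(10, 20), c(100, 50)), c(0.1, 0.4))
  expect_error(relative_response(50, 0), "internal standard")
  expect_error(relative_response(50, -1), "internal standard")
})

test_that("OLS fit recovers a noiseless line exactly and flags flat responses", {
  s <- noiseless_series(slope = 2, intercept = 0)
  f <- fit_calibration(s)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$concentration_range, c(0.001, 500))
  flat <- calibration_series(c(1, 2, 3), c(50, 50, 50), c(100, 100, 100))
  ff <- fit_calibration(flat)
  expect_equal(ff$slope, 0)
  expect_true(ff$noninformative)
  expect_error(calibration_series(c(2, 2, 2), c(1, 2, 3), c(1, 1, 1)),
               "degenerate")
  expect_error(calibration_series(c(1, 2), c(1, 2), c(1, 1)), "3 points")
})

test_that("fit recovers the true slope within 3 standard errors on noisy series", {
  spec <- calibration_sim_spec(true_slope = 0.6, true_intercept = 0.002,
                               noise_sd = 0.05, seed = 31)
  ok <- 0L
  for (seed in 31:40) {
    spec$seed <- seed
    s <- generate_calibration_series(spec, "solvent")
    f <- fit_calibration(s)
    lmfit <- lm(relative_response ~ nominal_concentration, data = s)
    se <- summary(lmfit)$coefficients["nominal_concentration", "Std. Error"]
    if (abs(f$slope - 0.6) <= 3 * se) ok <- ok + 1L
  }
  expect_gte(ok, 9L)  # ~99.7% coverage per draw; allow one excursion in ten
})

test_that("quantification inverts the calibration line and flags out-of-range values", {
  s <- noiseless_series(slope = 2, intercept = 0)
  f <- fit_calibration(s)
  expect_equal(as.numeric(quantify(f, 4)), 2.0, tolerance = 1e-12)
  expect_equal(as.numeric(quantify(f, f$intercept)), 0)
  # negative back-calculation clamps to zero with a flag
  q <- quantify(f, -1)
  expect_equal(as.numeric(q), 0)
  expect_true(attr(q, "below_range"))
  # beyond the top level: extrapolation flag
  q2 <- quantify(f, 2 * 600)
  expect_true(attr(q2, "extrapolated"))
  expect_error(quantify(fit_calibration(
    calibration_series(c(1, 2, 3), c(5, 5, 5), c(10, 10, 10))), 1),
    "zero-slope")
})

test_that("round-trip quantify(fit(series), response(c)) returns c for noiseless lines", {
  set.seed(99)
  for (i in 1:20) {
    slope <- runif(1, 0.1, 5)
    intercept <- runif(1, -0.05, 0.05)
    s <- noiseless_series(slope, intercept)
    f <- fit_calibration(s)
    conc <- default_calibration_levels()
    rr <- slope * conc + intercept
    expect_equal(as.numeric(quantify(f, rr)), conc, tolerance = 1e-8)
  }
})

test_that("R^2 is invariant under joint rescaling of concentrations and responses", {
  spec <- calibration_sim_spec(0.6, 0.002, noise_sd = 0.05, seed = 17)
  s <- generate_calibration_series(spec, "solvent")
  f1 <- fit_calibration(s)
  s2 <- calibration_series(s$nominal_concentration * 1000,
                           s$analyte_area * 7, s$is_area,
                           medium = attr(s, "medium"))
  f2 <- fit_calibration(s2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("LOD/LOQ follow the blank-SD formula with the exact 10/3 ratio", {
  # hand arithmetic: sigma_bl = 0.002, slope = 0.6 -> LOD 0.01, LOQ 0.0333;
  # sd(c(a - d, a + d)) = d * sqrt(2), so pick d for a sample SD of exactly 0.002
  b <- blank_set(c(0.01 - 0.002 / sqrt(2), 0.01 + 0.002 / sqrt(2)))
  expect_equal(b$sd_blank, 0.002, tolerance = 1e-12)
  curve <- fit_calibration(noiseless_series(0.6))
  ll <- lod_loq(b, curve)
  expect_equal(ll[["lod"]], 0.01, tolerance = 1e-10)
  expect_equal(ll[["loq"]], 0.1 / 3, tolerance = 1e-10)
  # degenerate blanks: zero SD -> zero limits
  ll0 <- lod_loq(blank_set(c(0.4, 0.4, 0.4)), curve)
  expect_equal(unname(ll0), c(0, 0))
  # ratio identity across random blank sets and slopes
  set.seed(4)
  for (i in 1:10) {
    bb <- blank_set(rnorm(20, 0.02, runif(1, 1e-4, 1e-2)))
    cv <- fit_calibration(noiseless_series(runif(1, 0.1, 3)))
    r <- lod_loq(bb, cv)
    expect_equal(r[["loq"]] / r[["lod"]], 10 / 3, tolerance = 1e-12)
  }
  expect_error(lod_loq(b, fit_calibration(
    calibration_series(c(1, 2, 3), c(5, 5, 5), c(10, 10, 10)))), "positive")
})

test_that("the literal blank-mean LOD variant scales the blank mean instead of its SD", {
  b <- blank_set(c(0.009, 0.011, 0.010, 0.010))  # mean 0.01
  curve <- fit_calibration(noiseless_series(0.6))
  ll <- lod_loq(b, curve, method = "blank_mean")
  expect_equal(ll[["lod"]], 3 * 0.01 / 0.6, tolerance = 1e-12)
  expect_equal(ll[["loq"]] / ll[["lod"]], 10 / 3, tolerance = 1e-12)
})

test_that("inverse-concentration weighting is available and needs positive levels", {
  spec <- calibration_sim_spec(0.6, 0, noise_sd = 0.02, seed = 8)
  s <- generate_calibration_series(spec, "solvent")
  fw <- fit_calibration(s, weighting = "inv_x")
  expect_true(is.finite(fw$slope))
  s0 <- calibration_series(c(0, 1, 2), c(0, 10, 20), c(10, 10, 10))
  expect_error(fit_calibration(s0, weighting = "inv_x"), "positive")
})
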
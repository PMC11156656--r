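adult <- exposure_profile("adult", 114.3, 70)
child <- exposure_profile("child", 35, 15)

test_that("method-of-moments lognormal fit matches hand-checked values and round-trips", {
  expect_equal(unname(fit_lognormal_moments(exp(1), 0)), c(1, 0))
  p <- fit_lognormal_moments(10.33, 5.5)
  expect_equal(unname(p["mu"]), 2.2102, tolerance = 1e-4)
  expect_equal(unname(p["sigma"]), 0.4997, tolerance = 1e-3)
  p2 <- fit_lognormal_moments(1.48, 1.0)
  expect_equal(unname(p2["mu"]), 0.2040, tolerance = 1e-3)
  expect_equal(unname(p2["sigma"]), 0.6133, tolerance = 1e-3)
  expect_error(fit_lognormal_moments(0, 1), "arith_mean")
  # round-trip identities to 1e-10 relative over random targets
  set.seed(2)
  for (i in 1:25) {
    m <- runif(1, 0.05, 50); s <- runif(1, 0, 3 * m)
    q <- fit_lognormal_moments(m, s)
    expect_equal(exp(q["mu"] + q["sigma"]^2 / 2) / m, c(mu = 1),
                 tolerance = 1e-10)
    var_ln <- (exp(q["sigma"]^2) - 1) * exp(2 * q["mu"] + q["sigma"]^2)
    expect_equal(unname(var_ln), s^2, tolerance = 1e-8)
  }
})

test_that("CDI converts units once and matches hand arithmetic", {
  expect_equal(cdi(0, adult), 0)
  expect_equal(cdi(10.33, adult), 1.6867e-5, tolerance = 1e-4)
  expect_equal(cdi(0.85, child), 1.9833e-6, tolerance = 1e-4)
  expect_error(cdi(-1, adult), ">= 0")
})

test_that("hazard quotient is CDI over RfDo", {
  expect_equal(hazard_quotient(0, 0.01), 0)
  expect_equal(hazard_quotient(1.6867e-5, 0.01), 1.6867e-3)
  expect_equal(hazard_quotient(1, 0.2), 2 * hazard_quotient(1, 0.4))
  expect_error(hazard_quotient(1, 0), "> 0")
})

test_that("closed-form HQ p95 oracle matches hand arithmetic and is monotone in sigma", {
  m <- lognormal_concentration_model("x", exp(0.5), sqrt((exp(1) - 1) * exp(1)))
  # that model has mu = 0, sigma = 1 by construction
  expect_equal(m$mu, 0, tolerance = 1e-10)
  expect_equal(m$sigma, 1, tolerance = 1e-10)
  expect_equal(hq_p95_closed_form(m, adult, 0.01), 8.4585e-4, tolerance = 1e-4)
  # sigma = 0: p95 equals the deterministic HQ at exp(mu)
  m0 <- lognormal_concentration_model("x", 10, 0)
  expect_equal(hq_p95_closed_form(m0, adult, 0.01),
               hazard_quotient(cdi(10, adult), 0.01), tolerance = 1e-12)
  # monotone increasing in sigma at fixed mu (fixed median, growing tail)
  p95_at_sigma <- function(sg) {
    mm <- m0; mm$sigma <- sg
    hq_p95_closed_form(mm, adult, 0.01)
  }
  sg <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(sg, p95_at_sigma, numeric(1))) > 0))
})

test_that("Monte-Carlo HQ p95 tracks the closed-form quantile within its sampling error", {
  # analytic SE of the empirical p95 of a lognormal: sqrt(p(1-p)/n) / f(q),
  # so the relative SE is sqrt(p(1-p)/n) * sigma / dnorm(z_0.95)
  z <- qnorm(0.95)
  for (sigma in c(0.5, 1, 1.5)) {
    m <- lognormal_concentration_model("x", exp(sigma^2 / 2),
                                       sqrt((exp(sigma^2) - 1) * exp(sigma^2)))
    expect_equal(m$mu, 0, tolerance = 1e-9)
    sim <- simulate_hq(m, adult, 0.01, n_replicates = 1e5, seed = 101)
    oracle <- hq_p95_closed_form(m, adult, 0.01)
    rel_se <- sqrt(0.95 * 0.05 / 1e5) * sigma / dnorm(z)
    expect_lt(abs(sim$hq_p95 - oracle) / oracle, 3 * rel_se)
  }
  # degenerate point mass: every draw identical
  m0 <- lognormal_concentration_model("x", 10, 0)
  sim0 <- simulate_hq(m0, adult, 0.01, n_replicates = 1000, seed = 1)
  expect_equal(sim0$hq_mean, 1.63286e-3, tolerance = 1e-5)
  expect_equal(sim0$hq_p95, sim0$hq_mean, tolerance = 1e-12)
  expect_error(simulate_hq(m0, adult, 0.01, n_replicates = 0), "n_replicates")
})

test_that("common random numbers scale HQ exactly by the profile intake ratio", {
  m <- lognormal_concentration_model("x", 10.33, 5.5)
  sa <- simulate_hq(m, adult, 0.01, n_replicates = 2e4, seed = 7,
                    keep_draws = TRUE)
  sc <- simulate_hq(m, child, 0.01, n_replicates = 2e4, seed = 7,
                    keep_draws = TRUE)
  ratio <- (35 / 15) / (114.3 / 70)
  expect_equal(ratio, 1.42897, tolerance = 1e-4)
  expect_equal(sc$draws, sa$draws * ratio, tolerance = 1e-12)
  expect_equal(sc$hq_p95 / sa$hq_p95, ratio, tolerance = 1e-12)
})

test_that("lognormal parameters are recovered from 1e5 simulated draws within 1%", {
  m <- lognormal_concentration_model("x", 10.33, 5.5)
  conc <- carbrisk:::with_substream(55, "recovery", rlnorm(1e5, m$mu, m$sigma))
  refit <- fit_lognormal_moments(mean(conc), sd(conc))
  expect_lt(abs(refit["mu"] - m$mu) / m$mu, 0.01)
  expect_lt(abs(refit["sigma"] - m$sigma) / m$sigma, 0.01)
})

test_that("hazard index sums per-pesticide percentiles and matches the oracle on the fixture", {
  expect_equal(hazard_index(c(0.001, 0.002, 0)), 0.003)
  expect_warning(hi0 <- hazard_index(numeric(0)), "no pesticides")
  expect_equal(hi0, 0)
  expect_error(hazard_index(c(0.1, -0.1)), ">= 0")
  fx <- study_fixture(seed = 1)
  models <- concentration_models(fx$residue_spec$pesticides,
                                 names(fx$rfdo_table))
  res <- assess_risk(models, fx$rfdo_table, fx$profiles$adult,
                     n_replicates = 1e5, seed = 3)
  oracle_hi <- sum(vapply(models, function(m)
    hq_p95_closed_form(m, fx$profiles$adult, fx$rfdo_table[[m$pesticide]]),
    numeric(1)))
  expect_lt(abs(res$hi - oracle_hi) / oracle_hi, 0.01)
  expect_true(all(res$per_pesticide$hq_p95 >= 0))
  expect_equal(res$hi, sum(res$per_pesticide$hq_p95))
})

test_that("pesticides without a reference dose are excluded with a notice", {
  fx <- study_fixture(seed = 1)
  models <- concentration_models(fx$residue_spec$pesticides)  # all 14
  expect_message(
    res <- assess_risk(models, fx$rfdo_table, fx$profiles$adult,
                       n_replicates = 500, seed = 1),
    "excluded")
  expect_equal(nrow(res$per_pesticide), 6)
  expect_length(res$excluded, 8)
})

test_that("the per-replicate HQ-sum diagnostic bounds the headline HI from above", {
  fx <- study_fixture(seed = 1)
  models <- concentration_models(fx$residue_spec$pesticides,
                                 names(fx$rfdo_table))
  res <- assess_risk(models, fx$rfdo_table, fx$profiles$adult,
                     n_replicates = 2e4, seed = 5, diagnostics = TRUE)
  # sum of marginal p95s >= p95 of the sum (subadditivity of the quantile
  # aggregate used here)
  expect_lte(res$hi_sum_p95, res$hi)
})
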
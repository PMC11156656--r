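---
title: "From peak areas to hazard indices: methods behind carbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From peak areas to hazard indices: methods behind carbrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbrisk)
```

carbrisk re-implements, as a tested pipeline, the post-acquisition
computational chain of a pesticide-residue monitoring study: once an
LC-MS/MS instrument has produced peak areas, everything downstream —
calibration, detection limits, matrix effects, validation statistics,
measurement uncertainty, regulatory screening, and consumer risk — is
arithmetic that should be reproducible to the last digit. This vignette
describes each model in that chain, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## Internal-standard calibration

Quantification uses the relative response $y = A_{\text{analyte}} /
A_{\text{IS}}$, the ratio of the analyte peak area to that of an
isotopically labeled internal standard spiked at a fixed level. A straight
line $y = m c + b$ is fitted by ordinary least squares over the 12-level
series 0.001–500 µg kg⁻¹ (`default_calibration_levels()`). Unweighted OLS
is the default; over a five-decade range the high levels dominate the fit,
so a $1/c$ weighting option is provided (`weighting = "inv_x"`) but kept
off by default, matching the common practice of reporting a single
unweighted $R^2$. Unknowns are back-calculated as $\hat c = (y - b)/m$;
negative back-calculations occur legitimately for signals near the blank
and are clamped to zero with a `below_range` flag rather than erroring,
while values outside the fitted range carry an `extrapolated` flag.

A degenerate series whose responses are all equal carries no concentration
information; `fit_calibration()` returns slope 0 with a `noninformative`
flag instead of failing, so screening pipelines can skip such analytes
explicitly.

## Detection and quantification limits

From $n = 20$ replicate blank measurements the mean blank signal
$\bar S_{bl}$ and its standard deviation $\sigma_{bl}$ are estimated (with
the sample, $n-1$, denominator: twenty blanks are a sample). The minimum
distinguishable signal is $S_m = \bar S_{bl} + k \sigma_{bl}$ with $k = 3$
for LOD and $k = 10$ for LOQ — the S/N ≥ 3 / ≥ 10 convention — and
converting the excess over the blank through the calibration slope gives

$$c_m = \frac{S_m - \bar S_{bl}}{m} = \frac{k\,\sigma_{bl}}{m}.$$

Some reports print the algebraic shortcut $c_m = k \bar S_{bl} / m$, which
does not follow from the threshold derivation (it scales the blank *mean*,
not its spread). The package implements the $\sigma_{bl}$ form as the
default and retains the blank-mean variant behind
`lod_loq(..., method = "blank_mean")` purely so that published numbers
computed that way can be audited. Under either method LOQ/LOD $= 10/3$
identically, and zero blank spread gives LOD = LOQ = 0.

## Matrix effect

Ion suppression or enhancement is quantified by comparing slopes of
calibration curves prepared in pure solvent and in blank matrix:

$$\mathrm{ME}\,(\%) = 100 \times \frac{m_{\text{matrix}} -
\text{m}_{\text{solvent}}}{m_{\text{solvent}}}.$$

Effects within ±20 % are classified *soft* (negligible; solvent-matched
calibration is acceptable), beyond that *significant* (matrix-matched
calibration required). The boundary is treated as inclusive-soft: the
guideline wording places "from −20 to 20 %" in the negligible class, so
±20 itself is soft. `matrix_effect()` consumes two fitted curves rather
than raw series so that the fit policy lives in one place.

## Validation statistics

Recovery at a spike level is $100 \times \bar x / c_{\text{spike}}$ with
the SANTE acceptance window 60–140 % (inclusive). Precision is the
relative standard deviation $100 \times s/\bar x$ with the ≤ 20 % ceiling
(inclusive), computed intraday (per day, plus a pooled-within-day
combination) and interday. The interday figure pools all replicates across
days — the convention behind "12 replicates (6 analyses per day)"
reporting — rather than decomposing variance; a one-way random-effects
decomposition (`interday = "anova"`) is available as a diagnostic. The two
conventions differ slightly even for identical days: duplicating a day
leaves the spread unchanged but shrinks the $n-1$ denominator, so the
pooled interday RSD is $\sqrt{10/11}$ of the intraday RSD at $n = 6$,
while the ANOVA variant recovers exact equality. Sample ($n-1$) SDs are
used throughout this module.

## Measurement uncertainty

The top-down route estimates uncertainty from the validation data alone.
With per-replicate relative bias $b_i = (x_i - c_{\text{true}})/
c_{\text{true}}$,

$$u_{\text{bias}} = \sqrt{\overline{b}^2 + \mathrm{SD.P}(b)^2}, \qquad
u_{\text{prec}} = \mathrm{RSD}_{\text{interday}}/100, \qquad
u = \sqrt{u_{\text{bias}}^2 + u_{\text{prec}}^2}, \qquad
U = 100\,k\,u,$$

with coverage factor $k = 2$ (≈ 95 % coverage) and the regulatory ceiling
$U \le 50\,\%$ (inclusive). Two deliberate conventions: the bias SD uses
the population ($n$) denominator — it describes the spread of the observed
biases themselves — while every other SD in the package is a sample SD;
and all internal quantities are fractions, only $U$ is rendered in
percent, which prevents the %-versus-fraction mixing these formulas
invite. Note a structural property of this estimator: when bias and
precision are computed from the *same* replicates, the replicate spread
enters twice (once inside $\mathrm{SD.P}(b)$, once as the precision RSD),
so for a simulated method with bias $\beta$ and CV $\rho$ the large-$n$
limit of $u$ is $\sqrt{\beta^2 + \rho^2(1+\beta)^2 + \rho^2}$, slightly
above the naive $\sqrt{\beta^2+\rho^2}$. The tests assert the exact limit.

## Residue screening

Survey summaries are computed over *detected* samples only (reported
ranges and means in monitoring tables exclude non-detects), with detection
and exceedance percentages relative to all samples. Exceedance is strict
($c > \mathrm{MRL}$): a residue exactly at the limit complies, the usual
regulatory reading, and since published tables never report an exactly-at
case the boundary had to be decided here. Percentages are exact rationals
internally — 21 of 55 is 38.1818… % — and rounded to one decimal only at
display time. Because the mean-of-detects convention is a choice, both the
SD and the standard error of the detects accompany every mean.

## Probabilistic risk assessment

Per pesticide, residue concentrations are modeled as lognormal with the
arithmetic mean and SD matched by method of moments:

$$\mu = \ln\!\frac{m^2}{\sqrt{m^2+s^2}}, \qquad
\sigma = \sqrt{\ln\!\left(1 + s^2/m^2\right)},$$

so $\exp(\mu + \sigma^2/2) = m$ exactly. The Monte-Carlo chain draws
$10^5$ concentrations, converts µg kg⁻¹ to mg kg⁻¹, and computes the
chronic daily intake and hazard quotient

$$\mathrm{CDI} = \frac{C \times \mathrm{IR}}{\mathrm{BW}}, \qquad
\mathrm{HQ} = \frac{\mathrm{CDI}}{\mathrm{RfDo}},$$

with fixed consumer profiles (adult: 114.3 g day⁻¹, 70 kg; child:
35 g day⁻¹, 15 kg — only the concentration is stochastic). The hazard
index is the sum over pesticides of the 95th-percentile HQs, computed with
the linear-interpolation empirical quantile (`stats::quantile`, type 7) so
results are bit-reproducible given a seed; HI < 1 is read as no
non-carcinogenic risk. Pesticides without a published chronic oral
reference dose are excluded from the HI with a logged notice. Because a
scaled lognormal is lognormal, the p95 has the closed form
$\exp(\mu + z_{0.95}\sigma)$ times the intake constants; that expression
(`hq_p95_closed_form()`) is the independent oracle against which the
Monte-Carlo machinery is tested, and with common random numbers the child
and adult HQ draws differ by the exact factor
$(35/15)/(114.3/70) \approx 1.42897$.

Two aggregation subtleties are surfaced rather than hidden. The headline
HI sums *marginal* 95th percentiles; the 95th percentile of the
per-replicate HQ *sum* is a different (for independent components,
typically smaller) number and is available as a clearly labeled diagnostic
(`diagnostics = TRUE`). And the per-pesticide random substreams are keyed
by pesticide name, not by position, so adding or removing a pesticide does
not perturb the others' draws.

## The study fixture and its dispersion ambiguity

`study_fixture()` encodes a 14-carbamate survey of 55 date-fruit samples:
per-pesticide detection frequencies, observed ranges, means, method LODs
(used as censor limits), MRLs (10 µg kg⁻¹ for most analytes; 5 for
propoxur, 3 for carbofuran, 30 for methiocarb), reference doses for six
analytes, and the two consumer profiles. Survey summary tables of this
kind print a mean "± dispersion" without saying whether the dispersion is
a standard deviation or a standard error, and here the printed values
(e.g. 10.33 ± 0.19 against a 2.54–24.77 range) are far too small to be
sample SDs. The package therefore offers both readings:
`dispersion = "printed"` takes the value literally as the SD, and
`dispersion = "range"` (the default) uses the range heuristic
$s \approx (\max - \min)/4$, which is the interpretation consistent with
the hazard-index scale this scenario is known for. The risk stage of the
pipeline and the acceptance script run both, and the safety conclusion
(HI < 1) is insensitive to the choice by more than two orders of
magnitude.

## What the generators emulate — and what they do not

The synthetic survey draws, per pesticide, an independent Bernoulli
"present at all" indicator at the configured detection frequency, then a
lognormal concentration for present samples, censored at the LOD either by
marking sub-LOD draws as non-detects (`"censor"`, the default — observed
detection frequencies in real surveys arise this way) or by redrawing
(`"truncate"`, which guarantees no detect below the LOD). This reproduces
the *marginal* statistical structure of a monitoring campaign: detection
rates, detect-only moments, exceedance counts. It deliberately does not
emulate correlation between pesticides within a sample, spatial or
varietal structure among samples, measurement error on reported
concentrations, or any dependence of detectability on concentration beyond
the censoring itself (thinning is independent of magnitude — a documented
simplification). Passing tests on this generator therefore validate the
pipeline's arithmetic and its statistical conventions, not the ecological
realism of any particular survey.

Calibration series are simulated with homoscedastic Gaussian noise on the
relative response and a multiplicative slope perturbation in matrix
medium; real instrument noise is closer to proportional at high levels,
which is precisely why the `inv_x` weighting option exists. Spike
replicates are Gaussian around the biased expectation with CV `rsd_frac`.

All randomness flows from one master seed through named substreams
(`substream_seed()`), so every stage can be regenerated independently and
identical seeds give byte-identical outputs end to end.

## Problem sizes and numerical tolerances

The test suite runs the risk chain at $10^5$ replicates (the study-scale
Monte-Carlo, a few seconds per profile) and the generator-fidelity checks
at $2\times10^4$–$5\times10^4$ samples, sized so that Monte-Carlo standard
errors are several times smaller than the asserted tolerances: empirical
moments within 2 % of targets, MC p95 within three analytic standard
errors of the closed-form quantile ($\mathrm{rel.\,SE} =
\sqrt{p(1-p)/n}\,\sigma/\phi(z_{0.95})$, about 0.33 % at $\sigma = 0.5$),
moment-fit round-trips to $10^{-10}$ relative. Equality-at-boundary tests
(recovery 60/140, RSD 20, ME ±20, the 50 % uncertainty ceiling) are built
from exactly representable values so they test the inclusive boundary, not
floating-point luck.

## Known limitations

- Areas arrive precomputed; there is no peak integration, and no
  chromatogram or spectrum model.
- Per-analyte linear-range trimming (reporting a narrower dynamic range
  than the fitted levels) is left to the user; the curve records the range
  of the data it was fitted on.
- Screening is per-pesticide; no cumulative-MRL logic.
- The risk model randomizes concentration only; intake and body weight
  are fixed constants per profile, and no acute (ARfD) or carcinogenic
  (slope-factor) endpoints are modeled.
- Non-detect handling in the risk stage follows the detects-only summary
  statistics; substitution policies (0, LOD/2) can be explored by editing
  the fixture's spec, but no automated sensitivity analysis is shipped.

The package is organized as an analysis workflow — numbered driver scripts
under `analysis/` narrate the stages and write their tables under
`results/`, while every computation lives in the package so the tests and
the acceptance script exercise the same code paths.
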
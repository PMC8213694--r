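---
title: "Methods: quantifying changing water constraints on vegetation growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying changing water constraints on vegetation growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcoupling)
```

## The scientific question

Vegetation growth can be limited by too little water (drylands) or,
counter-intuitively, by too much of it (waterlogged or energy-limited
ecosystems, where a dry spell brings more sun and warmth). `vegcoupling`
implements a statistical pipeline for asking whether, where, and at what
timescale vegetation growth is coupled to water availability in multi-decadal
monthly records, and whether that coupling is changing over time. The package
is indicator-agnostic: any monthly vegetation proxy (an NDVI-like index, VOD,
EVI, SIF, GPP) and any standardized water-availability index can be supplied
as gridded cubes.

The pipeline is exercised end-to-end on synthetic gridded data with planted,
recorded ground truth, so every stage has a parameter-recovery test rather
than only plausibility checks.

## The model, stage by stage

### Water-availability indexing (SPEI)

The climatic water balance is `D = P - PET` (precipitation minus potential
evapotranspiration, mm/month). For a timescale `k` in 1..24 months, `D` is
summed over the trailing `k` months, and the `k`-month sums of each grid cell
and calendar month are standardized by fitting a three-parameter log-logistic
distribution (scale `alpha > 0`, shape `beta > 1`, origin `gamma`) by
unbiased probability-weighted moments and mapping through the inverse normal:
`SPEI = qnorm(F(D_k))`. A value of 0 is the local median balance; -1.28 is
the 10th percentile. Assumptions: the water balance distribution is stable
over the calibration period (default: the full record, configurable), and
the log-logistic is an adequate family for `k`-month sums.

Numerical choices:

* The inverse normal uses `stats::qnorm` (error far below 1e-8, equivalent
  to the rational approximations used in the classical construction).
* Output is clipped to ±3.5 (configurable): beyond that range the empirical
  calibration carries no information.
* The log-logistic is positively skewed. A cell/month slot whose samples are
  left-skewed (a real finite-sample event when `D` is nearly symmetric) has
  no valid direct fit; such slots are fitted on the sign-reflected sample
  and the CDF is mirrored back. This keeps the family and the
  standardization property (per-slot mean ≈ 0, sd ≈ 1 over calibration)
  intact for either skew, and is verified by a property test.
* Degenerate slots (constant samples, invalid shape) yield `NA` SPEI rather
  than aborting a grid; a single-vector `fit_loglogistic()` call on constant
  input is an error, by contract.

An scPDSI-style fixed-timescale index is never computed internally; any
standardized cube can be supplied in that role.

### Vegetation anomalies

Monthly z-scores per cell and calendar month: `A = (x - mean_m) / sd_m`,
with the **sample** (n−1) standard deviation; the convention is recorded in
the `climatology` object. Slots with zero variance become invalid, not
infinite. The reference period defaults to the full record.

### Coupling classification

For each cell, the Spearman rank correlation between the growing-season
(April–October) anomaly and the water index is computed over pairs **pooled
monthly across years**: 7 × 34 = 238 pairs for a full 1982–2015 record, 35
pairs per 5-year window. The alternative layout (annual growing-season
means) is retained as a switch (`layout = "annual"`), but 5 annual means per
window cannot support a p < 0.05 screen, which is why monthly pooling is the
default. Significant positive correlation (p < 0.05, t-approximation) marks
a *water-deficit* cell, significant negative a *water-surplus* cell;
otherwise none. Correlations with fewer than 10 complete pairs are invalid.

Moving windows (5 years by default; 10 and 15 supported) recompute the
correlation from window-local pairs while anomalies keep the full-record
climatology — windows then differ only in sampling, not in baseline. Class
area fractions use a constant denominator (all valid vegetated cells), and
their trends across windows are screened with *both* the OLS t-test and the
Mann–Kendall test, the convention used for the headline area trends.

### Trend tests

`linear_trend()` is OLS on (index, value) with a two-sided t-test;
`mann_kendall()` computes S, the tie-corrected variance, and a
continuity-corrected normal deviate. Exhaustive oracles (all 120 orderings
of 5 pairs for Spearman; all 3^6 series on {1,2,3} with a 720-permutation
variance oracle for MK) pin both down exactly.

A deliberate limitation replicated from standard practice: moving windows
overlap (adjacent 5-year windows share 4/5 of their samples), so
window-statistic series are strongly autocorrelated, and plain trend tests
applied to them reject a stationary null far above the nominal level (our
null simulations measure ≈ 0.35 at α = 0.05 with the both-tests screen).
The pipeline applies the plain tests anyway — that is the published
procedure — but the package documents that per-cell "significant trends" of
windowed statistics are descriptive, not calibrated inferences. Under a
planted drift of the coupling (|rho| 0.2 → 0.8 across windows) detection
power exceeds 95%, which the acceptance suite verifies.

### Response time and surplus period

Correlating the anomaly with SPEI at every timescale k = 1..24 yields a
per-cell profile. The *minimum deficit response time* is the smallest k with
a significant positive correlation; the *maximum surplus period* is the
largest k with a significant negative one; both can coexist in a cell.
Windowed versions recompute profiles from window-local pairs (per-window
significance, same α); a trend is reported only when at least 10 of the
windows have a defined value, to avoid trends fitted to sparse series.

Identifiability caveat, and why the generator has coupling modes: physically
nested SPEI channels share months, so a vegetation signal carried by the
`k`-month sum also correlates with every shorter sum (corr ≈ sqrt(k'/k)),
and with 238 pairs those cascades are significant — the minimum rule would
always return 1. The generator therefore offers:

* `coupling = "lagged"`: the anomaly responds to the standardized water
  balance of the single month k−1 months back. That month is contained in
  every aggregation of length ≥ k and in none shorter, so the minimum rule
  has a well-defined target while the channels stay physically nested.
* `timescale_mode = "independent"`: each timescale channel is drawn
  independently, used for windowed-profile recovery where per-window
  significance (35 pairs) needs a strong in-window signal.

Even under the most favorable construction the minimum rule carries an
irreducible error: each of the k−1 shorter timescales is a null test with a
one-sided 2.5% false-positive rate at α = 0.05, so exact recovery decays
with the planted k (measured ≈ 1.00 / 0.95 / 0.92 / 0.88 for k* = 1/3/6/12
in the acceptance suite). This is a property of the published rule, not of
the implementation.

### Drought-conditioned anomaly trend

Long-term vegetation trends are removed before isolating drought effects:
either piecewise-linear over consecutive 5-year blocks (the default,
matching the short-interval convention and absorbing slow non-linear
drifts; whole-series OLS is the `block = Inf` switch) or a centered
12-month moving average (half-weights at the window ends, the classical
decomposition filter). Detrended growing-season anomalies of all cell-months
under drought — SPEI03 < −1.28, or an scPDSI-style index < −1, strict
inequalities, reported separately per index rather than pooled — are
averaged per year, and the annual series is tested for trend. Annual
aggregation suppresses seasonal sampling imbalance; years with no flagged
sample are invalid. The result provably depends only on flagged cell-months
(a permutation test in the suite).

### Attribution

Per cell, the 30-window coupling series is regressed on four drivers
averaged over each window's growing season: precipitation, air temperature,
shortwave radiation, and the global CO2 series (identical across cells).
The overall F-test of the raw-value regression screens cells (p < 0.05);
the *dominant factor* is the driver with the largest absolute **partial
Spearman correlation** (ranks first, then partial correlation given the
other three). Two algebraically equivalent partial-correlation routes —
residual-on-residual and the inverse-correlation-matrix identity — are both
implemented and must agree to 1e−10, which guards the linear algebra. Exact
ties are broken by the fixed driver order Pre, Rad, Tmp, CO2 and flagged.

Relative importance uses the exact LMG decomposition: with four predictors
the 2^4 subset R² values are enumerated and each driver's sequential
increment is averaged over all 4! orderings. Shares are non-negative and
sum to the full-model R² (identity asserted to 1e−10 on every input).
The window-level response is autocorrelated for the same overlap reason as
above; the screening F-test inherits that liberality and is documented as
such.

## The synthetic world

`synth_config()` defaults describe the study conditions: a 20 × 20 grid,
408 months (1982–2015), growing season April–October, vegetation anomaly
noise sd 0.3, coupling magnitude 0.5, planted timescale 3 months, 5% of
cells masked invalid, and an aridity gradient spanning arid through humid
(AI 0.05–1.2). Climate is seasonal with July peaks: gamma precipitation
whose mean tracks `AI × PET` (so the long-run P/PET ratio reproduces the
aridity map), positive PET, Gaussian temperature and radiation, and a
strictly increasing CO2 ramp (341 ppm + 0.15 ppm/month). Temperature and
radiation trends default to zero so that planted driver dominance is the
only low-frequency structure; both are configurable. Dominance is planted
as a shared latent linear component added to the dominant driver, scaled to
twice the driver's window-mean noise (SNR 2); grid-level CO2 dominance
relies on the CO2 ramp itself, and the matrix-level fixture
(`simulate_attribution_cells()`) plants any of the four columns directly.

Vegetation raw values are `climatology + 0.08 × anomaly` on a seasonal
climatology (base 0.5, amplitude 0.25), so the z-score stage must actually
invert the construction rather than pass data through. Coupling drift is
linear in time — the simplest structure a moving-window trend must recover.

What the generator does **not** emulate: spatial autocorrelation, realistic
climate physics (no Penman–Monteith, no soil water balance), orbital or
sensor artifacts, and drought event structure beyond what the index
thresholds induce. Passing recovery tests therefore demonstrate that the
statistical machinery recovers known structure at realistic noise levels —
not that real-world attribution is identified.

## Problem sizes and runtime

All tests and the acceptance script run on desk-scale problems chosen as
the package's own convention: the default 20 × 20 × 408-month grid for the
end-to-end run (about half a minute), 200-cell grids for recovery
simulations, 1,000 cells for null calibration, 10^4 replicates for trend
test size, and exhaustive enumeration (120 and 729 cases) for the rank
statistics. The full suite completes in a few minutes on one CPU.

## Known limitations

* Overlapping-window trend screens are anti-conservative (measured, see
  above); treat per-cell window-trend significance as descriptive.
* The minimum/maximum-significant-timescale rules inherit multiplicity
  error from 24 per-cell tests at a fixed α; no correction is applied, by
  design fidelity.
* Grid cells are counted, not area-weighted; no spatial multiple-testing
  correction is applied across cells.
* The scPDSI-style index is consumed, never computed.
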
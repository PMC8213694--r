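# vegcoupling

Tools for quantifying how strongly — and at which timescale — vegetation
growth is coupled to water availability, and whether that coupling is
changing over multi-decadal monthly records.

## Who this is for

Ecohydrologists and remote-sensing analysts working with gridded monthly
time series: a vegetation proxy (NDVI-like index, VOD, EVI, SIF, GPP, …),
precipitation and potential evapotranspiration (or a precomputed
standardized water index), plus climate drivers. The package implements the
full statistical chain and ships a synthetic-data generator with recorded
ground truth, so every stage has a parameter-recovery test.

## What it computes

* **Multi-timescale SPEI.** The water balance `D = P − PET` is accumulated
  over k = 1..24 months and standardized per cell and calendar month by a
  three-parameter log-logistic fit (unbiased probability-weighted moments)
  mapped through the inverse normal: `SPEI = Φ⁻¹(F(D_k))`.
* **Anomalies.** Monthly z-scores `A = (x − x̄_m) / σ_m` against a per-cell,
  per-calendar-month climatology (sample sd).
* **Coupling regimes.** Per cell, the Spearman correlation between
  growing-season (Apr–Oct) anomalies and a water index over monthly pairs
  pooled across years (238 pairs for 1982–2015). Significant positive
  (p < 0.05) ⇒ *water-deficit* cell; significant negative ⇒ *water-surplus*
  cell. Moving windows (5/10/15 years) give per-window correlations, class
  maps, and regime area fractions whose trends are screened with both an
  OLS t-test and the tie-corrected Mann–Kendall test.
* **Response time.** Per cell, the minimum SPEI timescale with a
  significant positive correlation (*minimum deficit response time*) and
  the maximum timescale with a significant negative one (*maximum surplus
  period*), their windowed series and trends.
* **Drought-conditioned trend.** After piecewise-linear or moving-average
  detrending, the annual mean anomaly over all drought-flagged cell-months
  (SPEI03 < −1.28; scPDSI-style index < −1) is tested for trend.
* **Attribution.** Per cell, the window coupling series is screened with a
  four-driver regression F-test (precipitation, temperature, radiation,
  CO₂); the dominant driver is the largest absolute partial Spearman
  correlation, and the exact LMG decomposition splits the model R² into
  non-negative per-driver shares.

## Worked example

Plant a 4 × 4 world in which half the cells are water-limited (deficit) and
half waterlogged (surplus), with coupling strength drifting from 0.05 to
0.7 over 1982–2015, then recover the structure:

```r
library(vegcoupling)

cfg <- synth_config(ny = 4, nx = 4, seed = 42,
                    regime = matrix(rep(c("deficit", "surplus"), 8), 4, 4),
                    timescale = 3L, timescales = 1:6,
                    b_start = 0.05, b_end = 0.7)
ds <- synth_dataset(cfg)
anom <- monthly_zscore(ds$veg)

## full-period coupling map
cm <- couple_cells(anom, ds$spei$spei03)
print(cm)
#> <coupling_map> none=0 deficit=8 surplus=7 invalid=1

## expanding deficit / shrinking surplus area across 5-year windows
ws <- moving_windows(anom, ds$spei$spei03, window = 5)
aft <- area_fraction_trend(ws)
aft$series[c(1, 15, 30), ]
#>    start_year   deficit   surplus      none
#> 1        1982 0.2000000 0.3333333 0.4666667
#> 15       1996 0.5333333 0.4666667 0.0000000
#> 30       2011 0.5333333 0.4666667 0.0000000
aft$trend$deficit
#> <trend_result> n=30 slope=0.004405 (p=0.00261) | MK S=108 Z=3.25 (p=0.00115) -> increasing
```

Reading the output: over the full period all 15 valid cells are classified
into their planted regimes (one cell is masked as unvegetated). In the
earliest 5-year window the coupling is still too weak to detect, so only
20% / 33% of cells screen in; as the planted coupling strengthens, the
deficit area fraction grows, and both trend tests flag the expansion
(slope ≈ 0.44 percentage points of area per window, p < 0.01).

The whole chain — indices, coupling, response time, drought trend,
attribution — runs end to end from one config:

```r
run_pipeline(list(out_dir = "out", seed = 1))   # writes CSV + NetCDF + manifest
```

or from the shell via the thin wrapper
`Rscript inst/cli/vegcoupling.R run --seed 1 --out-dir out`.

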
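test_that("configuration invariants are enforced", {
  expect_error(synth_config(ny = 0), "1 x 1")
  expect_error(synth_config(end_year = 1989), "10 years")
  expect_error(synth_config(b_start = 1.5), "lie in")
  expect_error(synth_config(regime = "wet"), "values must be in")
  expect_error(synth_config(regime = matrix("deficit", 3, 3)), "matrix")
  expect_error(synth_config(timescale = 5L, timescales = 1:3), "planted")
  expect_error(synth_config(co2_drift = 0), "positive")
})

test_that("the domain spans all four aridity classes along the gradient", {
  cfg <- synth_config(ny = 1, nx = 4, ai_range = c(0.1, 0.8))
  dom <- make_domain(cfg)
  expect_equal(as.vector(dom$aridity_class),
               c("arid", "semi-arid", "sub-humid", "humid"))
  expect_true(all(dom$ai >= 0))
  # determinism and the mask fraction contract
  dom2 <- make_domain(cfg)
  expect_identical(dom, dom2)
  all_valid <- make_domain(synth_config(mask_fraction = 0))
  expect_true(all(all_valid$mask))
  frac <- make_domain(synth_config(mask_fraction = 0.25))
  expect_equal(sum(!frac$mask), 100)   # 25% of 400 cells
})

test_that("simulated climate respects support and monotonicity constraints", {
  cfg <- synth_config(ny = 3, nx = 3, seed = 5)
  clim <- simulate_climate(cfg, make_domain(cfg))
  expect_true(min(clim$pre$data) >= 0)
  expect_true(min(clim$pet$data) > 0)
  expect_true(all(diff(clim$co2) > 0))
  for (cb in clim[c("pre", "pet", "tmp", "rad")])
    expect_identical(cube_calendar(cb), cube_calendar(clim$pre))
})

test_that("trend-free climate is stationary across decades", {
  cfg <- synth_config(ny = 5, nx = 5, seed = 6, tmp_trend = 0, rad_trend = 0,
                      mask_fraction = 0)
  clim <- simulate_climate(cfg, make_domain(cfg))
  tmp <- clim$tmp
  early <- tmp$year <= tmp$year[1] + 9
  late <- tmp$year >= max(tmp$year) - 9
  n_sig <- 0L; n_tot <- 0L
  for (ix in 1:5) for (iy in 1:5) for (m in c(1, 4, 7, 10)) {
    a <- tmp$data[early & tmp$month == m, iy, ix]
    b <- tmp$data[late & tmp$month == m, iy, ix]
    n_tot <- n_tot + 1L
    if (t.test(a, b)$p.value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lt(n_sig / n_tot, 0.05)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- synth_config(ny = 2, nx = 2, seed = 11, timescales = 1:3)
  a <- synth_dataset(cfg)
  b <- synth_dataset(cfg)
  expect_identical(a$veg$data, b$veg$data)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(lapply(a$spei, `[[`, "data"), lapply(b$spei, `[[`, "data"))
  expect_identical(a$truth, b$truth)
})

test_that("planted regimes produce the expected correlation signs", {
  reg <- matrix(c("deficit", "surplus"), 2, 3)
  ds <- synth_dataset(synth_config(ny = 2, nx = 3, seed = 12, regime = reg,
                                   timescale = 2L, timescales = 1:2,
                                   b_start = 0.7, b_end = 0.7,
                                   mask_fraction = 0))
  prof <- timescale_profile(ds$anomaly, ds$spei)
  for (ix in 1:3) {
    expect_gt(prof$rho[2, 1, ix], 0.5)    # deficit row
    expect_lt(prof$rho[2, 2, ix], -0.5)   # surplus row
  }
  # noiseless coupling is a perfect monotone transform
  ds0 <- synth_dataset(synth_config(ny = 1, nx = 1, seed = 13, noise_sd = 0,
                                    timescale = 2L, timescales = 1:2,
                                    b_start = 0.8, b_end = 0.8,
                                    mask_fraction = 0))
  sel <- season_selector(ds0$anomaly)
  sc <- spearman_cor(ds0$anomaly$data[sel, 1, 1], ds0$spei$spei02$data[sel, 1, 1])
  expect_equal(sc$rho, 1)
})

test_that("null cells trigger the classifier at close to the nominal rate", {
  ds <- synth_dataset(synth_config(ny = 25, nx = 40, seed = 14,
                                   regime = "none", timescale = 1L,
                                   timescales = 1L,
                                   timescale_mode = "independent",
                                   mask_fraction = 0))
  cm <- couple_cells(monthly_zscore(ds$veg), ds$spei$spei01)
  rate <- mean(cm$class %in% c("deficit", "surplus"))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("ground truth round-trips through JSON without loss", {
  ds <- small_dataset(seed = 15)
  f <- tempfile(fileext = ".json")
  write_truth(ds$truth, f)
  back <- read_truth(f)
  expect_identical(back$regime, ds$truth$regime)
  expect_identical(back$timescale, ds$truth$timescale)
  expect_equal(back$drift_sign, ds$truth$drift_sign)
  expect_identical(back$dominant, ds$truth$dominant)
  expect_identical(back$seed, ds$truth$seed)
  unlink(f)
})

test_that("a missing planted timescale cube is an error", {
  cfg <- synth_config(ny = 1, nx = 1, timescale = 3L, timescales = 1:3)
  ds <- synth_dataset(cfg)
  expect_error(simulate_vegetation(cfg, ds$spei[1:2]), "missing")
})
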
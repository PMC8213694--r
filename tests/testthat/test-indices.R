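test_that("monthly z-scores invert the climatology construction", {
  # 3 years, each calendar month taking values {1, 2, 3}: sample sd = 1,
  # so anomalies are exactly -1, 0, 1
  dat <- array(rep(1:3, each = 12), c(36, 1, 1))
  cube <- grid_cube(dat, 2000)
  a <- monthly_zscore(cube)
  expect_equal(as.numeric(a$data), rep(c(-1, 0, 1), each = 12))

  # a cube sitting exactly on the climatology means gives all-zero anomalies
  vary <- toy_cube(nt = 36, ny = 1, nx = 1, seed = 8)
  clim <- monthly_climatology(vary)
  on_mean <- grid_cube(array(rep(clim$mean[, 1, 1], 3), c(36, 1, 1)), 2000)
  expect_true(all(abs(monthly_zscore(on_mean, clim)$data) < 1e-12))
  expect_identical(clim$sd_convention, "sample")
})

test_that("constant cells become invalid rather than infinite", {
  dat <- array(5, c(36, 1, 2))
  dat[, 1, 2] <- rnorm(36)
  a <- monthly_zscore(grid_cube(dat, 2000))
  expect_true(all(is.na(a$data[, 1, 1])))
  expect_true(all(is.finite(a$data[, 1, 2])))
})

test_that("water balance is elementwise with mask/NA propagation", {
  P <- toy_cube(nt = 24, seed = 1)
  PET <- toy_cube(nt = 24, seed = 2)
  expect_true(all(abs(water_balance(P, P)$data) < 1e-15))
  P2 <- P; P2$data[] <- 50
  PET2 <- PET; PET2$data[] <- 80
  expect_true(all(water_balance(P2, PET2)$data == -30))
  P3 <- P; P3$data[3, 1, 1] <- NA
  expect_true(is.na(water_balance(P3, PET)$data[3, 1, 1]))
  shifted <- grid_cube(P$data, 2001)
  expect_error(water_balance(P, shifted), "aligned")
})

test_that("k-month aggregation sums a backward window", {
  D <- grid_cube(array(c(1, 2, 3, 4), c(4, 1, 1)), 2000)
  expect_equal(as.numeric(aggregate_k(D, 1)$data), c(1, 2, 3, 4))
  d3 <- as.numeric(aggregate_k(D, 3)$data)
  expect_true(all(is.na(d3[1:2])))
  expect_equal(d3[3:4], c(6, 9))
  long <- toy_cube(nt = 48)
  for (k in c(2, 5, 12))
    expect_equal(sum(is.na(aggregate_k(long, k)$data[, 1, 1])), k - 1)
  expect_error(aggregate_k(long, 25), "1..24")
})

test_that("log-logistic PWM fit recovers known parameters", {
  set.seed(10)
  x <- qllog3(runif(1e5), alpha = 10, beta = 3, gamma = 0)
  fit <- fit_loglogistic(x)
  expect_lt(abs(fit["alpha"] - 10) / 10, 0.02)
  expect_lt(abs(fit["beta"] - 3) / 3, 0.02)
  expect_lt(abs(fit["gamma"]), 0.2)   # origin error on the alpha=10 scale

  y <- qllog3(runif(1e4), alpha = 5, beta = 4, gamma = 2)
  f2 <- fit_loglogistic(y)
  expect_lt(abs(pllog3(median(y), f2["alpha"], f2["beta"], f2["gamma"]) - 0.5),
            0.02)
  expect_error(fit_loglogistic(rep(3, 50)), "degenerate")
})

test_that("SPEI standardizes each calendar-month slot over calibration", {
  set.seed(11)
  cube <- grid_cube(array(rnorm(480 * 2 * 2, -10, 30), c(480, 2, 2)), 1980)
  Dk <- aggregate_k(cube, 3)
  sp <- compute_spei(Dk, fit_spei_params(Dk))
  for (ix in 1:2) for (iy in 1:2) {
    m <- tapply(sp$data[, iy, ix], sp$month, mean, na.rm = TRUE)
    s <- tapply(sp$data[, iy, ix], sp$month, sd, na.rm = TRUE)
    expect_lt(max(abs(m)), 0.05)
    expect_lt(max(abs(s - 1)), 0.1)
  }
  # monotone in Dk within a calendar-month slot
  jan <- which(Dk$month == 1)
  ord <- order(Dk$data[jan, 1, 1])
  expect_true(!is.unsorted(sp$data[jan, 1, 1][ord], na.rm = TRUE))
})

test_that("SPEI is invariant to a constant shift of the water balance", {
  set.seed(12)
  D <- grid_cube(array(rnorm(420, 0, 20), c(420, 1, 1)), 1980)
  D2 <- grid_cube(D$data + 57.3, 1980)
  mk_spei <- function(d) {
    dk <- aggregate_k(d, 6)
    compute_spei(dk, fit_spei_params(dk))$data
  }
  expect_equal(mk_spei(D), mk_spei(D2), tolerance = 1e-8)
})

test_that("aridity classes partition [0, Inf) with upper class at boundaries", {
  expect_equal(as.character(classify_aridity(0.1)), "arid")
  expect_equal(as.character(classify_aridity(0.7)), "humid")
  expect_equal(as.character(classify_aridity(0.5)), "sub-humid")
  expect_equal(as.character(classify_aridity(0.2)), "semi-arid")
  expect_equal(as.character(classify_aridity(0.65)), "humid")
  grid <- seq(0, 2, by = 0.01)
  cls <- classify_aridity(grid)
  expect_false(anyNA(cls))                      # every value in exactly one class
  expect_error(classify_aridity(-0.1), ">= 0")
  expect_identical(is_dryland(c("arid", "semi-arid", "sub-humid", "humid")),
                   c(TRUE, TRUE, TRUE, FALSE))
})

test_that("drought thresholds are strict inequalities", {
  fl <- flag_drought(c(-1.5, -1.28, -1.2), c(-1.5, -1, -0.5))
  expect_identical(fl$drought_spei, c(TRUE, FALSE, FALSE))
  expect_identical(fl$drought_scpdsi, c(TRUE, FALSE, FALSE))
})
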
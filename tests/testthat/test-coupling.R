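test_that("spearman_cor matches brute-force rank-Pearson on all 120 orderings", {
  x <- 1:5
  vals <- c(2.3, -1, 0.5, 7, 4)
  pm <- perms(5L)
  for (i in seq_len(nrow(pm))) {
    y <- vals[pm[i, ]]
    got <- spearman_cor(x, y, min_n = 3)
    expect_equal(got$rho, rank_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_cor handles monotone series, ties and short samples", {
  up <- spearman_cor(1:12, exp(1:12))
  expect_equal(up$rho, 1); expect_equal(up$p, 0)
  dn <- spearman_cor(1:12, -(1:12)^3)
  expect_equal(dn$rho, -1)
  # invariant to strictly increasing transforms of either argument
  set.seed(1)
  a <- rnorm(40); b <- a + rnorm(40)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(exp(a), b)$rho)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(a, atan(b))$rho)
  # below the minimum pair count: invalid, not an error
  short <- spearman_cor(1:5, 5:1, min_n = 10)
  expect_true(is.na(short$rho))
  expect_equal(short$n, 5)
  # NA pairs are dropped and n decremented
  b2 <- b; b2[c(3, 9)] <- NA
  expect_equal(spearman_cor(a, b2)$n, 38)
})

test_that("regime classification follows the sign/significance rule", {
  expect_equal(classify_coupling(0.4, 0.01, 100), "deficit")
  expect_equal(classify_coupling(-0.4, 0.01, 100), "surplus")
  expect_equal(classify_coupling(0.4, 0.2, 100), "none")
  expect_equal(classify_coupling(NA, NA, 5), "invalid")
  # a single correlation can never be both regimes
  set.seed(2)
  cls <- classify_coupling(runif(500, -1, 1), runif(500), rep(50, 500))
  expect_true(all(cls %in% c("deficit", "surplus", "none")))
})

test_that("season pairing pools the expected sample counts", {
  anom <- toy_cube(nt = 34 * 12, start_year = 1982, seed = 3)
  idx <- toy_cube(nt = 34 * 12, start_year = 1982, seed = 4)
  pairs <- season_pairs(anom, idx)                     # Apr-Oct, 34 years
  expect_equal(nrow(pairs(1, 1)), 7 * 34)
  jja <- season_pairs(anom, idx, season = 6:8, years = c(1990, 1994))
  expect_equal(nrow(jja(1, 1)), 15)
  # annual layout: one pair per year
  ann <- season_pairs(anom, idx, layout = "annual")
  expect_equal(nrow(ann(1, 1)), 34)
})

test_that("moving windows count years - window + 1 and use window pairs", {
  anom <- toy_cube(nt = 34 * 12, start_year = 1982, seed = 5)
  idx <- toy_cube(nt = 34 * 12, start_year = 1982, seed = 6)
  ws5 <- moving_windows(anom, idx, window = 5)
  expect_equal(length(ws5$start_years), 30)
  expect_equal(dim(ws5$rho)[1], 30)
  ws15 <- moving_windows(anom, idx, window = 15)
  expect_equal(length(ws15$start_years), 20)
  # window rho equals a direct correlation on that window's pairs
  sel <- anom$month %in% 4:10 & anom$year >= 1985 & anom$year <= 1989
  direct <- spearman_cor(anom$data[sel, 2, 1], idx$data[sel, 2, 1])
  expect_equal(ws5$rho[which(ws5$start_years == 1985), 2, 1], direct$rho)
})

test_that("area fractions partition the valid cells", {
  cls <- matrix("deficit", 10, 10)
  expect_equal(area_fraction(cls, "deficit"), 1)
  cls[1:25] <- "surplus"; cls[26:40] <- "none"
  mask <- matrix(TRUE, 10, 10)
  d <- area_fraction(cls, "deficit", mask)
  s <- area_fraction(cls, "surplus", mask)
  n <- area_fraction(cls, "none", mask)
  expect_equal(s, 0.25)
  expect_equal(d + s + n, 1)
})

test_that("area fraction uses a constant denominator across windows", {
  cls <- array("none", c(3, 2, 2))
  cls[1, 1, 1] <- "deficit"; cls[2, , ] <- "deficit"; cls[3, 1, 2] <- "deficit"
  mask <- matrix(TRUE, 2, 2)
  expect_equal(area_fraction(cls, "deficit", mask), c(0.25, 1, 0.25))
})
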
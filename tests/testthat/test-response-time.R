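fake_profile <- function(rho, p) {
  K <- length(rho)
  structure(list(rho = array(rho, c(K, 1, 1)), p = array(p, c(K, 1, 1)),
                 n = array(100L, c(K, 1, 1)), timescales = seq_len(K)),
            class = "timescale_profile")
}

test_that("min deficit response takes the smallest significant positive k", {
  rho <- rep(0.1, 24); p <- rep(0.5, 24)
  rho[c(4, 7, 12)] <- 0.5; p[c(4, 7, 12)] <- 0.01
  expect_equal(min_deficit_response(fake_profile(rho, p))[1, 1], 4L)
  expect_true(is.na(min_deficit_response(fake_profile(rep(0.1, 24), rep(0.5, 24)))[1, 1]))
  expect_equal(min_deficit_response(fake_profile(rep(0.5, 24), rep(0.001, 24)))[1, 1], 1L)
})

test_that("max surplus period takes the largest significant negative k", {
  rho <- rep(0.1, 24); p <- rep(0.5, 24)
  rho[c(2, 5)] <- -0.5; p[c(2, 5)] <- 0.01
  expect_equal(max_surplus_period(fake_profile(rho, p))[1, 1], 5L)
  rho2 <- rep(0.1, 24); p2 <- rep(0.5, 24)
  rho2[24] <- -0.4; p2[24] <- 0.03
  expect_equal(max_surplus_period(fake_profile(rho2, p2))[1, 1], 24L)
  expect_true(is.na(max_surplus_period(fake_profile(rep(0.1, 24), rep(0.5, 24)))[1, 1]))
})

test_that("deficit response and surplus period can coexist in one cell", {
  rho <- rep(0, 24); p <- rep(0.5, 24)
  rho[3] <- 0.5; p[3] <- 0.01      # deficit at short timescale
  rho[20] <- -0.5; p[20] <- 0.01   # surplus at long timescale
  pr <- fake_profile(rho, p)
  expect_equal(min_deficit_response(pr)[1, 1], 3L)
  expect_equal(max_surplus_period(pr)[1, 1], 20L)
})

test_that("a noiseless planted coupling gives a perfect profile entry", {
  ds <- synth_dataset(synth_config(ny = 1, nx = 2, seed = 3, noise_sd = 0,
                                   timescale = 3L, timescales = 1:3,
                                   b_start = 0.8, b_end = 0.8,
                                   mask_fraction = 0))
  prof <- timescale_profile(ds$anomaly, ds$spei)
  expect_equal(prof$rho[3, 1, 1], 1)
  expect_equal(prof$rho[3, 1, 2], 1)
})

test_that("a missing SPEI channel is an error before computation", {
  ds <- small_dataset()
  broken <- ds$spei
  broken[[2]] <- NULL
  broken <- c(broken[1], list(spei02 = NULL), broken[2])
  expect_error(timescale_profile(ds$anomaly, broken), "missing")
})

test_that("response-time trends need a minimum of defined windows", {
  rt <- array(NA_integer_, c(30, 1, 1))
  rt[c(2, 9, 17, 25), 1, 1] <- c(5L, 4L, 3L, 2L)   # only 4 defined
  tr <- response_time_trend(rt, min_defined = 10)
  expect_true(is.na(tr$slope[1, 1]))
  expect_equal(tr$n_defined[1, 1], 4L)
  rt2 <- array(rep(seq(12, 3, length.out = 30), 1), c(30, 1, 1))
  tr2 <- response_time_trend(rt2, min_defined = 10)
  expect_equal(tr2$direction[1, 1], "decreasing")
})

test_that("area summary of response-time change partitions the mask", {
  tr <- list(p = matrix(0.01, 2, 2), slope = matrix(-1, 2, 2),
             n_defined = matrix(30L, 2, 2),
             direction = matrix(c("decreasing", "increasing", "none", NA), 2, 2))
  s <- response_time_area_summary(tr)
  expect_equal(sum(s), 1)
  expect_equal(unname(s["decreased"]), 0.25)
})
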
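test_that("window driver means are linear in the window index for a ramp", {
  nt <- 34 * 12
  ramp <- seq(0, 10, length.out = nt)
  mk <- function(v) grid_cube(array(rep(v, 2), c(nt, 1, 2)), 1982)
  pre <- mk(ramp); tmp <- mk(rep(5, nt)); rad <- mk(ramp * 2)
  dm <- window_driver_means(pre, tmp, rad, co2 = 340 + 0.1 * seq_len(nt))
  expect_equal(dim(dm$X), c(30, 4, 1, 2))
  # constant driver -> constant column
  expect_true(all(abs(diff(dm$X[, "Tmp", 1, 1])) < 1e-12))
  # ramp -> equal window-to-window increments
  incr <- diff(dm$X[, "Pre", 1, 1])
  expect_lt(max(abs(incr - incr[1])), 1e-9)
  # CO2 column identical across cells
  expect_equal(dm$X[, "CO2", 1, 1], dm$X[, "CO2", 1, 2])
})

test_that("model screening detects perfect fits and rejects degenerate input", {
  set.seed(1)
  X <- matrix(rnorm(120), 30, 4)
  y <- 2 * X[, 1] - 1
  expect_lt(screen_model(y, X), 1e-6)
  expect_true(is.na(screen_model(rep(1, 30), X)))
  # null calibration at moderate rep count
  rej <- mean(replicate(400, screen_model(rnorm(30), matrix(rnorm(120), 30, 4)) < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("partial Spearman dual algorithms agree to numerical precision", {
  set.seed(2)
  for (r in 1:25) {
    X <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(NULL, c("Pre", "Tmp", "Rad", "CO2")))
    y <- rnorm(30)
    a <- partial_spearman(y, X, method = "residual")
    b <- partial_spearman(y, X, method = "matrix")
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("partial Spearman limits: empty conditioning set and pure drivers", {
  set.seed(3)
  x <- rnorm(40); y <- x + rnorm(40, sd = 0.5)
  solo <- partial_spearman(y, matrix(x, ncol = 1))
  expect_equal(unname(solo), spearman_cor(y, x)$rho, tolerance = 1e-12)
  # y driven by column 1 only, noise 0: |partial r1| ~ 1, others ~ 0
  X <- matrix(rnorm(200), 50, 4)
  y2 <- X[, 1]
  pr <- partial_spearman(y2, X)
  expect_gt(abs(pr[1]), 0.95)
  expect_lt(max(abs(pr[-1])), 0.35)
})

test_that("dominant factor follows max |partial| with screening and ties", {
  pr <- c(Pre = 0.6, Tmp = -0.7, Rad = 0.1, CO2 = 0.2)
  expect_equal(dominant_factor(pr, 0.01)$driver, "Tmp")
  expect_equal(dominant_factor(pr, 0.5)$driver, "none")
  tied <- c(Pre = 0.5, Tmp = 0.5, Rad = 0.1, CO2 = 0.1)
  dom <- dominant_factor(tied, 0.01)
  expect_equal(dom$driver, "Pre")    # fixed order Pre, Rad, Tmp, CO2
  expect_true(dom$tie)
})

test_that("LMG shares sum to R^2 and match closed forms", {
  set.seed(4)
  # identity on random data
  for (r in 1:10) {
    X <- matrix(rnorm(35 * 4), 35, 4)
    y <- rnorm(35)
    li <- lmg_importance(y, X)
    expect_lt(abs(sum(li$shares) - li$r2), 1e-10)
    expect_true(all(li$shares >= -1e-12))
  }
  # single predictor: share equals R^2
  x1 <- rnorm(30); y1 <- x1 + rnorm(30)
  l1 <- lmg_importance(y1, matrix(x1, ncol = 1))
  expect_equal(unname(l1$shares), l1$r2, tolerance = 1e-12)
  # exactly orthogonal standardized predictors: share_j = cor(y, x_j)^2
  Q <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))
  Q <- scale(Q)                        # centered, orthogonality preserved? re-orthogonalize
  Q <- qr.Q(qr(scale(Q, scale = FALSE)))
  y2 <- rnorm(40)
  l2 <- lmg_importance(y2, Q)
  expect_equal(unname(l2$shares), as.numeric(cor(y2, Q))^2, tolerance = 1e-10)
})

test_that("LMG matches a direct enumeration over all orderings", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- X %*% c(1, 0.5, 0, -0.3) + rnorm(30)
  li <- lmg_importance(y, X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  pm <- perms(4L)
  shares <- numeric(4)
  for (i in seq_len(nrow(pm))) {
    ord <- pm[i, ]
    for (pos in seq_along(ord)) {
      before <- if (pos > 1) ord[seq_len(pos - 1)] else integer(0)
      shares[ord[pos]] <- shares[ord[pos]] +
        (r2(c(before, ord[pos])) - r2(before)) / nrow(pm)
    }
  }
  expect_equal(unname(li$shares), shares, tolerance = 1e-10)
})

test_that("planted dominant drivers are recovered from window-level fixtures", {
  fx <- simulate_attribution_cells(120, snr = 2, seed = 6)
  hits <- 0L; sig <- 0L
  for (i in seq_len(120)) {
    y <- fx$y[, i]; X <- fx$X[, , i]
    mp <- screen_model(y, X)
    dom <- dominant_factor(partial_spearman(y, X), mp)
    if (dom$driver != "none") {
      sig <- sig + 1L
      if (dom$driver == fx$truth[i]) hits <- hits + 1L
    }
  }
  expect_gt(sig, 100)                 # the latent is strong enough to screen in
  expect_gt(hits / sig, 0.9)
})

test_that("dominant-driver area fractions sum to one within each regime", {
  dominant <- matrix(c("Pre", "Pre", "Rad", "none", "Tmp", "CO2"), 2, 3)
  attr <- structure(list(dominant = dominant, model_p = matrix(0.01, 2, 3)),
                    class = "attribution_map")
  cls <- matrix(c("deficit", "deficit", "deficit", "deficit",
                  "surplus", "surplus"), 2, 3)
  s <- dominant_area_summary(attr, cls)
  expect_equal(sum(s["deficit", ]), 1)
  expect_equal(unname(s["deficit", "Pre"]), 2 / 3)
  expect_equal(sum(s["surplus", ]), 1)
  # empty regime reported as missing
  s2 <- dominant_area_summary(attr, matrix("deficit", 2, 3))
  expect_true(all(is.na(s2["surplus", ])))
})
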
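#' Three-parameter log-logistic distribution
#'
#' CDF and quantile function of the log-logistic distribution with scale
#' `alpha > 0`, shape `beta > 0` and origin `gamma`, as used to standardize
#' cumulative water-balance series: F(x) = [1 + (alpha / (x - gamma))^beta]^-1
#' for x > gamma, 0 otherwise.
#'
#' @param q,p quantiles / probabilities.
#' @param alpha,beta,gamma distribution parameters.
#' @return numeric vector of probabilities (`pllog3`) or quantiles
#'   (`qllog3`).
#' @export
pllog3 <- function(q, alpha, beta, gamma = 0) {
  out <- numeric(length(q))
  pos <- is.finite(q) & q > gamma
  out[pos] <- 1 / (1 + (alpha / (q[pos] - gamma))^beta)
  out[!is.finite(q)] <- NA_real_
  out
}

#' @rdname pllog3
#' @export
qllog3 <- function(p, alpha, beta, gamma = 0) {
  gamma + alpha * (p / (1 - p))^(1 / beta)
}

#' Fit a log-logistic distribution by unbiased probability-weighted moments
#'
#' Fits the three-parameter log-logistic to a sample with the unbiased
#' probability-weighted moments w0, w1, w2 (decreasing-weight family,
#' exact binomial weights), the standard construction for SPEI:
#' beta = (2 w1 - w0) / (6 w1 - w0 - 6 w2),
#' alpha = (w0 - 2 w1) beta / (G(1 + 1/beta) G(1 - 1/beta)),
#' gamma = w0 - alpha G(1 + 1/beta) G(1 - 1/beta).
#'
#' @param x numeric sample (non-finite values dropped). At least 4 distinct
#'   finite values are required; fewer than 20 is flagged low-confidence.
#' @return named numeric vector `c(alpha, beta, gamma)` with attributes `n`
#'   (sample size) and `low_confidence` (fewer than 20 samples).
#' @examples
#' x <- qllog3(runif(1000), alpha = 10, beta = 3)
#' fit_loglogistic(x)
#' @export
fit_loglogistic <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite samples to fit a log-logistic")
  if (max(x) - min(x) <= 0)
    stop("degenerate fit: all samples are equal")
  x <- sort(x)
  i <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum((n - i) / (n - 1) * x) / n
  w2 <- sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * x) / n
  beta <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  if (!is.finite(beta) || beta <= 1)
    stop("degenerate fit: shape parameter outside the valid range")
  g1 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w0 - 2 * w1) * beta / g1
  if (!is.finite(alpha) || alpha <= 0)
    stop("degenerate fit: non-positive scale parameter")
  gamma0 <- w0 - alpha * g1
  structure(c(alpha = alpha, beta = beta, gamma = gamma0),
            n = n, low_confidence = n < 20L)
}

#' Fit SPEI standardization parameters for a k-month water-balance cube
#'
#' For every valid cell and calendar month, fits [fit_loglogistic()] to the
#' k-month aggregated water balance over the calibration period. Slots where
#' the fit is degenerate (constant samples, invalid shape) are left `NA`,
#' which propagates to invalid SPEI values rather than aborting the grid.
#'
#' @param Dk a [grid_cube] from [aggregate_k()].
#' @param calib_years length-2 integer vector (first, last year) of the
#'   calibration period; default: the full record.
#' @return object of class `spei_params`: list with `par` array of dim
#'   (12, ny, nx, 3) (alpha, beta, gamma), `n` array of sample counts,
#'   `low_confidence` and `reflected` logical arrays, `calib_years`.
#'
#' @details The log-logistic is positively skewed, so a slot whose samples
#'   happen to be left-skewed has no valid direct fit. Such slots are
#'   fitted on the sign-reflected sample and flagged `reflected`; the
#'   transform then uses the mirrored CDF, which keeps the distribution
#'   family and the standardization property intact for either skew.
#' @export
fit_spei_params <- function(Dk, calib_years = NULL) {
  stopifnot(inherits(Dk, "grid_cube"))
  if (is.null(calib_years)) calib_years <- range(Dk$year)
  d <- dim(Dk$data)
  par <- array(NA_real_, c(12L, d[2L], d[3L], 3L))
  nsl <- array(0L, c(12L, d[2L], d[3L]))
  lowc <- refl <- array(FALSE, c(12L, d[2L], d[3L]))
  sel_cal <- Dk$year >= calib_years[1L] & Dk$year <= calib_years[2L]
  for (m in 1:12) {
    rows <- which(sel_cal & Dk$month == m)
    for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
      if (!Dk$mask[iy, ix]) next
      smp <- Dk$data[rows, iy, ix]
      smp <- smp[is.finite(smp)]
      nsl[m, iy, ix] <- length(smp)
      fit <- tryCatch(fit_loglogistic(smp), error = function(e) NULL)
      if (is.null(fit)) {
        fit <- tryCatch(fit_loglogistic(-smp), error = function(e) NULL)
        if (!is.null(fit)) refl[m, iy, ix] <- TRUE
      }
      if (!is.null(fit)) {
        par[m, iy, ix, ] <- fit
        lowc[m, iy, ix] <- attr(fit, "low_confidence")
      }
    }
  }
  structure(list(par = par, n = nsl, low_confidence = lowc, reflected = refl,
                 calib_years = as.integer(calib_years)),
            class = "spei_params")
}

#' Standardized Precipitation-Evapotranspiration Index from fitted parameters
#'
#' Maps each k-month water-balance value through its cell/calendar-month
#' log-logistic CDF and the inverse standard normal: SPEI = qnorm(F(Dk)).
#' Over the calibration period this yields, per calendar month, mean close
#' to 0 and standard deviation close to 1. Values are clipped to
#' `+/- clip` (probabilities are clamped away from 0/1 accordingly); slots
#' without fitted parameters give `NA`.
#'
#' @param Dk a [grid_cube] from [aggregate_k()].
#' @param params a `spei_params` object fitted on the same k and calendar
#'   structure.
#' @param clip symmetric output range (default 3.5).
#' @return a [grid_cube] of SPEI values.
#' @export
compute_spei <- function(Dk, params, clip = 3.5) {
  stopifnot(inherits(Dk, "grid_cube"), inherits(params, "spei_params"))
  d <- dim(Dk$data)
  if (!identical(dim(params$par)[2:3], d[2:3]))
    stop("params grid does not match the cube grid")
  out <- array(NA_real_, d)
  pmin_ <- stats::pnorm(-clip)
  pmax_ <- stats::pnorm(clip)
  for (m in 1:12) {
    rows <- which(Dk$month == m)
    if (!length(rows)) next
    a <- params$par[m, , , 1L]
    b <- params$par[m, , , 2L]
    g <- params$par[m, , , 3L]
    rf <- params$reflected[m, , ]
    for (r in rows) {
      x0 <- matrix(Dk$data[r, , ], d[2L], d[3L])
      x <- ifelse(rf, -x0, x0)       # reflected slots were fitted on -sample
      F <- 1 / (1 + (a / (x - g))^b)
      below <- which(is.finite(x) & is.finite(g) & x <= g)
      F[below] <- 0
      F <- ifelse(rf, 1 - F, F)
      F <- pmin(pmax(F, pmin_), pmax_)
      F[!is.finite(x) | !is.finite(a)] <- NA_real_
      out[r, , ] <- stats::qnorm(F)
    }
  }
  grid_cube(out, Dk$year[1L], Dk$month[1L], mask = Dk$mask,
            varname = sub("^D", "spei", Dk$varname), units = "1")
}

#' Multi-timescale SPEI from precipitation and PET
#'
#' Convenience wrapper running [water_balance()], [aggregate_k()],
#' [fit_spei_params()] and [compute_spei()] for each requested timescale.
#'
#' @param P,PET aligned [grid_cube]s.
#' @param timescales integer vector of k values (default 1:24).
#' @param calib_years calibration period passed to [fit_spei_params()].
#' @param clip output range passed to [compute_spei()].
#' @return named list of SPEI [grid_cube]s, names `"spei01"`, `"spei02"`, ...
#' @export
spei_multiscale <- function(P, PET, timescales = 1:24, calib_years = NULL,
                            clip = 3.5) {
  D <- water_balance(P, PET)
  out <- lapply(timescales, function(k) {
    Dk <- aggregate_k(D, k)
    compute_spei(Dk, fit_spei_params(Dk, calib_years), clip = clip)
  })
  names(out) <- sprintf("spei%02d", timescales)
  out
}
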
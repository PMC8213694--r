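#' Ordinary least-squares linear trend test
#'
#' Fits `value ~ index` by OLS over the finite entries of `x` (the index is
#' the position in the series) and tests the slope against zero with a
#' two-sided t-test. A perfectly constant series is reported as slope 0 with
#' p = 1 rather than as an error; a perfect non-constant line gets p = 0.
#'
#' @param x numeric series; `NA`s are dropped (their index positions are
#'   kept, so gaps do not compress the time axis).
#' @return list with `slope`, `intercept`, `p`, `n`.
#' @examples
#' linear_trend(c(1, 2, 3, 4))$slope
#' @export
linear_trend <- function(x) {
  idx <- seq_along(x)
  ok <- is.finite(x)
  x <- x[ok]; idx <- idx[ok]
  n <- length(x)
  if (n < 3L) return(list(slope = NA_real_, intercept = NA_real_, p = NA_real_, n = n))
  mx <- mean(idx); my <- mean(x)
  sxx <- sum((idx - mx)^2)
  slope <- sum((idx - mx) * (x - my)) / sxx
  intercept <- my - slope * mx
  resid <- x - intercept - slope * idx
  rss <- sum(resid^2)
  if (rss <= 1e-14 * max(sum((x - my)^2), 1)) {
    ## exact fit: constant -> no trend; sloped line -> certain trend
    p <- if (abs(slope) < .Machine$double.eps^0.5) 1 else 0
    return(list(slope = slope, intercept = intercept, p = p, n = n))
  }
  se <- sqrt(rss / (n - 2L) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tval), df = n - 2L), n = n)
}

#' Mann-Kendall trend test with tie correction
#'
#' Computes the Mann-Kendall statistic S = sum over all pairs i < j of
#' sign(x_j - x_i), its variance with the standard correction for tied
#' groups, the continuity-corrected normal deviate Z (S shifted one unit
#' toward zero when nonzero), and the two-sided p-value.
#'
#' @param x numeric series; `NA`s dropped, order preserved.
#' @return list with `S`, `varS`, `Z`, `p`, `n`.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 5))$S
#' @export
mann_kendall <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(list(S = NA_integer_, varS = NA_real_, Z = NA_real_,
                          p = NA_real_, n = n))
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])          # sign(x_j - x_i), i < j: rows j > cols i
  tt <- table(x)
  varS <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  if (varS <= 0) {
    ## all values tied
    return(list(S = as.integer(S), varS = 0, Z = 0, p = 1, n = n))
  }
  Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  list(S = as.integer(S), varS = varS, Z = Z,
       p = 2 * stats::pnorm(-abs(Z)), n = n)
}

#' Combined trend assessment of a scalar series
#'
#' Runs [linear_trend()] and [mann_kendall()] and derives a trend direction
#' under a configurable significance convention. With `require = "both"`
#' (used for the area-fraction trends, where both tests are asserted) a
#' direction is declared only when both tests are significant at `alpha` and
#' the slope and S agree in sign; `"either"`, `"linear"` and `"mk"` relax
#' this to one test.
#'
#' @param x numeric series.
#' @param alpha significance level (default 0.05).
#' @param require which test(s) must be significant: `"both"`, `"either"`,
#'   `"linear"` or `"mk"`.
#' @return object of class `trend_result`: list with `slope`, `intercept`,
#'   `p_linear`, `S`, `varS`, `Z`, `p_mk`, `direction` in
#'   `c("increasing", "decreasing", "none")`, `n`, `alpha`, `require`.
#' @export
trend_test <- function(x, alpha = 0.05,
                       require = c("both", "either", "linear", "mk")) {
  require <- match.arg(require)
  lt <- linear_trend(x)
  mk <- mann_kendall(x)
  sig_lin <- is.finite(lt$p) && lt$p < alpha
  sig_mk <- is.finite(mk$p) && mk$p < alpha
  sig <- switch(require,
                both = sig_lin && sig_mk,
                either = sig_lin || sig_mk,
                linear = sig_lin,
                mk = sig_mk)
  dir <- "none"
  if (sig) {
    s_lin <- sign(lt$slope)
    s_mk <- sign(mk$S)
    agree <- switch(require,
                    both = s_lin == s_mk && s_lin != 0,
                    either = TRUE,
                    linear = s_lin != 0,
                    mk = s_mk != 0)
    if (agree) {
      s <- if (require == "mk") s_mk else s_lin
      if (s > 0) dir <- "increasing" else if (s < 0) dir <- "decreasing"
    }
  }
  structure(list(slope = lt$slope, intercept = lt$intercept, p_linear = lt$p,
                 S = mk$S, varS = mk$varS, Z = mk$Z, p_mk = mk$p,
                 direction = dir, n = lt$n, alpha = alpha, require = require),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> n=%d slope=%.4g (p=%.3g) | MK S=%s Z=%.3g (p=%.3g) -> %s\n",
              x$n, x$slope, x$p_linear, format(x$S), x$Z, x$p_mk, x$direction))
  invisible(x)
}
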
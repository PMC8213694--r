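#' Remove a significant linear trend from a series
#'
#' Tests the OLS trend of the series; when significant at `alpha`, subtracts
#' the fitted slope component while preserving the series mean. A series
#' without a significant trend is returned unchanged (bit-identical). The
#' operation is idempotent: the detrended series has OLS slope 0 to
#' numerical tolerance.
#'
#' @param x numeric (monthly) series, at least 24 values recommended.
#' @param alpha significance level for the trend screen (default 0.05; use
#'   `alpha = 1` to always remove the slope).
#' @return numeric series, same length.
#' @export
detrend_linear <- function(x, alpha = 0.05) {
  lt <- linear_trend(x)
  if (!is.finite(lt$p) || lt$p >= alpha) return(x)
  idx <- seq_along(x)
  ok <- is.finite(x)
  x - lt$slope * (idx - mean(idx[ok]))
}

#' Remove piecewise-linear trends over consecutive year blocks
#'
#' Splits the record into consecutive `block`-year intervals (a shorter
#' final block is allowed) and applies [detrend_linear()] within each: the
#' short-interval variant of trend removal, which also absorbs slow
#' non-linear drifts. Whole-series removal is the `block = Inf` limit.
#'
#' @param x numeric monthly series.
#' @param years integer vector of calendar years, one per entry of `x`.
#' @param block block length in years (default 5).
#' @param alpha per-block significance screen (default 0.05).
#' @return numeric series, same length.
#' @export
detrend_piecewise <- function(x, years, block = 5L, alpha = 0.05) {
  stopifnot(length(x) == length(years))
  if (!is.finite(block)) return(detrend_linear(x, alpha))
  y0 <- min(years)
  grp <- (years - y0) %/% as.integer(block)
  out <- x
  for (g in unique(grp)) {
    sel <- grp == g
    out[sel] <- detrend_linear(x[sel], alpha)
  }
  out
}

#' Remove a centered moving-average trend
#'
#' Estimates the slow (interannual) component with a centered moving average
#' -- for an even span the two end months of the window get half weight, the
#' classical seasonal-decomposition filter -- and returns the residual.
#' Months where the window is incomplete are `NA`.
#'
#' @param x numeric monthly series longer than `span`.
#' @param span window span in months (default 12, centered).
#' @return numeric series: `x` minus its moving-average trend; edges `NA`.
#' @export
detrend_moving_average <- function(x, span = 12L) {
  span <- as.integer(span)
  if (length(x) <= span) stop("series must be longer than the span")
  w <- if (span %% 2L == 0L) c(0.5, rep(1, span - 1L), 0.5) / span
       else rep(1, span) / span
  trend <- stats::filter(x, w, method = "convolution", sides = 2)
  x - as.numeric(trend)
}

#' Detrend every cell of a cube
#'
#' @param cube a [grid_cube].
#' @param method `"linear"` (whole series), `"piecewise"` (consecutive
#'   `block`-year intervals) or `"moving_average"`.
#' @param alpha significance screen for the linear methods.
#' @param block block length in years for `"piecewise"`.
#' @param span months for `"moving_average"`.
#' @return a [grid_cube] of detrended values.
#' @export
detrend_cube <- function(cube, method = c("piecewise", "linear", "moving_average"),
                         alpha = 0.05, block = 5L, span = 12L) {
  method <- match.arg(method)
  d <- dim(cube$data)
  out <- cube$data
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    if (!cube$mask[iy, ix]) next
    x <- cube$data[, iy, ix]
    out[, iy, ix] <- switch(method,
      linear = detrend_linear(x, alpha),
      piecewise = detrend_piecewise(x, cube$year, block, alpha),
      moving_average = detrend_moving_average(x, span))
  }
  grid_cube(out, cube$year[1L], cube$month[1L], mask = cube$mask,
            varname = paste0(cube$varname, "_dt"), units = cube$units)
}

#' Trend of drought-conditioned vegetation anomalies
#'
#' Pools, for each year, the detrended growing-season anomalies of all
#' cell-months flagged as drought, and tests the annual mean series for
#' trend. A steadily more negative series means drought events depress
#' vegetation growth more strongly over time. Years without any flagged
#' sample are invalid and skipped by the trend test. The result depends
#' only on flagged cell-months.
#'
#' @param anom detrended anomaly [grid_cube].
#' @param flags logical array, same dim as `anom$data` (e.g. one element of
#'   [flag_drought()]).
#' @param season months pooled (default April-October).
#' @param alpha significance level.
#' @param require trend-test convention (see [trend_test()]; default
#'   `"linear"`).
#' @return list with data.frame `series` (`year`, `mean_anomaly`,
#'   `n_samples`) and `trend` (a [trend_test()] result, or `NULL` when
#'   fewer than 3 years have samples).
#' @export
drought_anomaly_trend <- function(anom, flags, season = 4:10, alpha = 0.05,
                                  require = "linear") {
  stopifnot(inherits(anom, "grid_cube"))
  if (!identical(dim(flags), dim(anom$data)))
    stop("`flags` must have the same dimensions as the anomaly cube")
  sel_t <- season_selector(anom, season)
  mask3 <- aperm(array(anom$mask, c(dim(anom$data)[2:3], dim(anom$data)[1L])),
                 c(3L, 1L, 2L))
  use <- flags & mask3 & is.finite(anom$data)
  use[!sel_t, , ] <- FALSE
  yrs <- sort(unique(anom$year))
  mean_a <- rep(NA_real_, length(yrs))
  n_s <- integer(length(yrs))
  for (i in seq_along(yrs)) {
    rows <- which(anom$year == yrs[i])
    u <- use[rows, , , drop = FALSE]
    n_s[i] <- sum(u)
    if (n_s[i] > 0L) mean_a[i] <- mean(anom$data[rows, , ][u])
  }
  ser <- data.frame(year = yrs, mean_anomaly = mean_a, n_samples = n_s)
  tr <- if (sum(is.finite(mean_a)) >= 3L)
    trend_test(mean_a, alpha = alpha, require = require) else NULL
  list(series = ser, trend = tr)
}
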
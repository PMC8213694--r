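#' Per-cell correlation profile across SPEI timescales
#'
#' For each valid cell, correlates the vegetation anomaly with the water
#' index at every timescale k supplied (conventionally 1..24 months) over
#' the pooled growing-season pairs.
#'
#' @param anom anomaly [grid_cube].
#' @param spei_list named list of SPEI [grid_cube]s, one per timescale, in
#'   increasing k order (as from [spei_multiscale()]). All must share the
#'   anomaly cube's calendar; a missing timescale is an error before any
#'   computation.
#' @param season,years,min_n as in [couple_cells()].
#' @return object of class `timescale_profile`: list with arrays `rho`, `p`,
#'   `n` of dim (K, ny, nx) and the vector `timescales`.
#' @export
timescale_profile <- function(anom, spei_list, season = 4:10, years = NULL,
                              min_n = 10L) {
  K <- length(spei_list)
  if (K == 0L) stop("`spei_list` is empty")
  for (k in seq_len(K)) {
    if (is.null(spei_list[[k]]))
      stop(sprintf("SPEI cube for timescale %d is missing", k))
    stop_unless_aligned(anom, spei_list[[k]],
                        sprintf("anomaly and SPEI[%d] cubes", k))
  }
  d <- dim(anom$data)
  rho <- p <- array(NA_real_, c(K, d[2L], d[3L]))
  n <- array(0L, c(K, d[2L], d[3L]))
  sel <- season_selector(anom, season, years)
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    if (!anom$mask[iy, ix]) next
    a <- anom$data[sel, iy, ix]
    for (k in seq_len(K)) {
      sc <- spearman_cor(a, spei_list[[k]]$data[sel, iy, ix], min_n = min_n)
      rho[k, iy, ix] <- sc$rho; p[k, iy, ix] <- sc$p; n[k, iy, ix] <- sc$n
    }
  }
  ks <- as.integer(sub("\\D*", "", names(spei_list)))
  if (any(is.na(ks))) ks <- seq_len(K)
  structure(list(rho = rho, p = p, n = n, timescales = ks),
            class = "timescale_profile")
}

## Smallest/largest timescale with a significant correlation of given sign
## for one profile column; NA when none qualifies.
.extreme_timescale <- function(rho, p, timescales, alpha, positive, minimum) {
  sig <- which(is.finite(p) & p < alpha &
                 if (positive) rho > 0 else rho < 0)
  if (!length(sig)) return(NA_integer_)
  as.integer(if (minimum) min(timescales[sig]) else max(timescales[sig]))
}

#' Minimum water-deficit response time
#'
#' The smallest SPEI timescale whose correlation with the vegetation anomaly
#' is significantly positive (p < alpha): how quickly a water shortfall is
#' first seen in vegetation growth. Undefined (`NA`) where no timescale
#' qualifies.
#'
#' @param profile a `timescale_profile`.
#' @param alpha significance level.
#' @return integer matrix (ny, nx); `NA` = undefined.
#' @export
min_deficit_response <- function(profile, alpha = 0.05) {
  stopifnot(inherits(profile, "timescale_profile"))
  d <- dim(profile$rho)
  out <- matrix(NA_integer_, d[2L], d[3L])
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L]))
    out[iy, ix] <- .extreme_timescale(profile$rho[, iy, ix], profile$p[, iy, ix],
                                      profile$timescales, alpha,
                                      positive = TRUE, minimum = TRUE)
  out
}

#' Maximum water-surplus period
#'
#' The largest SPEI timescale whose correlation with the vegetation anomaly
#' is significantly negative (p < alpha): the longest accumulation period
#' over which excess water still suppresses growth. Undefined (`NA`) where
#' no timescale qualifies. A cell may have both a deficit response time and
#' a surplus period (different signs at different timescales).
#'
#' @inheritParams min_deficit_response
#' @return integer matrix (ny, nx); `NA` = undefined.
#' @export
max_surplus_period <- function(profile, alpha = 0.05) {
  stopifnot(inherits(profile, "timescale_profile"))
  d <- dim(profile$rho)
  out <- matrix(NA_integer_, d[2L], d[3L])
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L]))
    out[iy, ix] <- .extreme_timescale(profile$rho[, iy, ix], profile$p[, iy, ix],
                                      profile$timescales, alpha,
                                      positive = FALSE, minimum = FALSE)
  out
}

#' Moving-window response-time series
#'
#' Recomputes the timescale profile within each moving window (window-local
#' pairs, same alpha) and extracts the per-window minimum deficit response
#' time and maximum surplus period.
#'
#' @inheritParams timescale_profile
#' @param window window length in years.
#' @param alpha significance level.
#' @return list with `start_years` and integer arrays `deficit_rt`,
#'   `surplus_period` of dim (n_windows, ny, nx).
#' @export
response_time_windows <- function(anom, spei_list, window = 5L, season = 4:10,
                                  alpha = 0.05, min_n = 10L) {
  yrs <- sort(unique(anom$year))
  window <- as.integer(window)
  if (length(yrs) < window) stop("record shorter than the window length")
  starts <- yrs[seq_len(length(yrs) - window + 1L)]
  d <- dim(anom$data)
  nw <- length(starts)
  rt <- sp <- array(NA_integer_, c(nw, d[2L], d[3L]))
  for (w in seq_len(nw)) {
    prof <- timescale_profile(anom, spei_list, season = season,
                              years = c(starts[w], starts[w] + window - 1L),
                              min_n = min_n)
    rt[w, , ] <- min_deficit_response(prof, alpha)
    sp[w, , ] <- max_surplus_period(prof, alpha)
  }
  list(start_years = starts, deficit_rt = rt, surplus_period = sp)
}

#' Per-cell trend of a windowed response-time series
#'
#' Linear trend test across the windows where the response time is defined;
#' a cell with fewer than `min_defined` defined windows is left undefined
#' (sparse series give spurious trends).
#'
#' @param rt_windows integer array (n_windows, ny, nx) from
#'   [response_time_windows()] (`deficit_rt` or `surplus_period`).
#' @param alpha significance level.
#' @param min_defined minimum defined windows for a trend (default 10).
#' @return list of matrices `slope`, `p`, `n_defined` and character matrix
#'   `direction` (`"increasing"`, `"decreasing"`, `"none"`, `NA` =
#'   undefined).
#' @export
response_time_trend <- function(rt_windows, alpha = 0.05, min_defined = 10L) {
  d <- dim(rt_windows)
  slope <- p <- matrix(NA_real_, d[2L], d[3L])
  nd <- matrix(0L, d[2L], d[3L])
  dirn <- matrix(NA_character_, d[2L], d[3L])
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    series <- as.numeric(rt_windows[, iy, ix])
    nd[iy, ix] <- sum(is.finite(series))
    if (nd[iy, ix] < min_defined) next
    lt <- linear_trend(series)
    slope[iy, ix] <- lt$slope; p[iy, ix] <- lt$p
    dirn[iy, ix] <- if (is.finite(lt$p) && lt$p < alpha) {
      if (lt$slope > 0) "increasing" else if (lt$slope < 0) "decreasing" else "none"
    } else "none"
  }
  list(slope = slope, p = p, n_defined = nd, direction = dirn)
}

#' Area summary of response-time change
#'
#' Fractions of valid cells with significantly decreasing / increasing
#' response-time (or surplus-period) trends.
#'
#' @param trend result of [response_time_trend()].
#' @param mask logical validity matrix; default: all cells with a defined
#'   trend assessment denominator, i.e. every non-`NA` entry of
#'   `trend$n_defined`.
#' @return named numeric vector `c(decreased, increased, no_change,
#'   undefined)` summing to 1.
#' @export
response_time_area_summary <- function(trend, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(trend$p), ncol(trend$p))
  total <- sum(mask)
  dirn <- trend$direction
  c(decreased = sum(dirn == "decreasing" & mask, na.rm = TRUE) / total,
    increased = sum(dirn == "increasing" & mask, na.rm = TRUE) / total,
    no_change = sum(dirn == "none" & mask, na.rm = TRUE) / total,
    undefined = sum(is.na(dirn) & mask) / total)
}
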
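#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks both arguments with average ranks for ties, computes the Pearson
#' correlation of the ranks, and derives a two-sided p-value from the
#' t-approximation t = rho sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees of
#' freedom. Pairs with a missing member are dropped first; below `min_n`
#' complete pairs the result is invalid (`NA`s), not an error.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum complete pairs for a valid result (default 10).
#' @return list with `rho`, `p`, `n`.
#' @examples
#' spearman_cor(1:12, (1:12)^3)        # rho = 1
#' @export
spearman_cor <- function(x, y, min_n = 10L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < max(min_n, 3L)) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

## Coupling regime byte codes used in NetCDF output.
REGIME_CODES <- c(none = 0L, deficit = 1L, surplus = 2L, invalid = 255L)

#' Classify a correlation into a coupling regime
#'
#' Water-deficit regime: significant positive correlation (vegetation grows
#' with wetness); water-surplus regime: significant negative correlation;
#' otherwise none. Results based on fewer than `min_n` pairs are invalid.
#'
#' @param rho,p,n vectors from [spearman_cor()] (recycled together).
#' @param alpha significance level (default 0.05).
#' @param min_n minimum sample count (default 10).
#' @return character vector in `c("deficit", "surplus", "none", "invalid")`.
#' @export
classify_coupling <- function(rho, p, n, alpha = 0.05, min_n = 10L) {
  stopifnot(alpha > 0, alpha < 1)
  out <- rep("none", length(rho))
  out[!is.finite(rho) | !is.finite(p) | n < min_n] <- "invalid"
  sig <- is.finite(p) & p < alpha & n >= min_n
  out[sig & rho > 0] <- "deficit"
  out[sig & rho < 0] <- "surplus"
  out
}

#' Growing-season sample pairs for one cell
#'
#' Pools the (anomaly, index) pairs of all season months across the given
#' year range -- the monthly-pooling layout (e.g. 7 months x 34 years = 238
#' pairs for a full April-October record). The alternative layout, annual
#' growing-season means, is available via `layout = "annual"`.
#'
#' @param anom,index aligned [grid_cube]s.
#' @param season integer months (default April-October, `4:10`).
#' @param years optional length-2 inclusive year range.
#' @param layout `"monthly"` (pool season months) or `"annual"` (one pair
#'   per year of season means).
#' @return function of `(iy, ix)` returning a two-column matrix of pairs;
#'   mostly used internally, exported for transparency of the sample layout.
#' @export
season_pairs <- function(anom, index, season = 4:10, years = NULL,
                         layout = c("monthly", "annual")) {
  layout <- match.arg(layout)
  stop_unless_aligned(anom, index, "anomaly and index cubes")
  sel <- season_selector(anom, season, years)
  yr <- anom$year[sel]
  function(iy, ix) {
    a <- anom$data[sel, iy, ix]
    b <- index$data[sel, iy, ix]
    if (layout == "annual") {
      a <- tapply(a, yr, mean, na.rm = TRUE)
      b <- tapply(b, yr, mean, na.rm = TRUE)
    }
    cbind(anom = as.numeric(a), index = as.numeric(b))
  }
}

#' Per-cell coupling between vegetation anomalies and a water index
#'
#' Computes, for every valid cell, the Spearman correlation over the pooled
#' growing-season pairs and classifies the regime.
#'
#' @inheritParams season_pairs
#' @param alpha significance level for classification.
#' @param min_n minimum complete pairs.
#' @return object of class `coupling_map`: list with matrices `rho`, `p`,
#'   `n`, character matrix `class`, plus `alpha`, `season`, `years`.
#' @export
couple_cells <- function(anom, index, season = 4:10, years = NULL,
                         alpha = 0.05, min_n = 10L,
                         layout = c("monthly", "annual")) {
  layout <- match.arg(layout)
  pairs <- season_pairs(anom, index, season, years, layout)
  d <- dim(anom$data)
  rho <- p <- matrix(NA_real_, d[2L], d[3L])
  n <- matrix(0L, d[2L], d[3L])
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    if (!anom$mask[iy, ix]) next
    pr <- pairs(iy, ix)
    sc <- spearman_cor(pr[, 1L], pr[, 2L], min_n = min_n)
    rho[iy, ix] <- sc$rho; p[iy, ix] <- sc$p; n[iy, ix] <- sc$n
  }
  cls <- matrix(classify_coupling(rho, p, n, alpha, min_n), d[2L], d[3L])
  cls[!anom$mask] <- "invalid"
  structure(list(rho = rho, p = p, n = n, class = cls, alpha = alpha,
                 season = season, years = years),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  tab <- table(factor(x$class, levels = names(REGIME_CODES)))
  cat("<coupling_map>", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Moving-window coupling series
#'
#' Slides a `window`-year window across the record (consecutive start years,
#' so `years - window + 1` windows; 30 five-year windows for a 34-year
#' record) and computes each window's per-cell Spearman correlation and
#' regime from that window's growing-season pairs only. Anomalies are taken
#' as supplied, i.e. standardized against the full-record climatology.
#'
#' @inheritParams couple_cells
#' @param window window length in years (5, 10 and 15 are the supported
#'   conventions).
#' @return object of class `window_series`: list with `start_years`,
#'   3-D arrays `rho` and `p` of dim (n_windows, ny, nx), character array
#'   `class`, `window`, `alpha`.
#' @export
moving_windows <- function(anom, index, window = 5L, season = 4:10,
                           alpha = 0.05, min_n = 10L) {
  stop_unless_aligned(anom, index, "anomaly and index cubes")
  yrs <- sort(unique(anom$year))
  window <- as.integer(window)
  if (length(yrs) < window) stop("record shorter than the window length")
  starts <- yrs[seq_len(length(yrs) - window + 1L)]
  d <- dim(anom$data)
  nw <- length(starts)
  rho <- p <- array(NA_real_, c(nw, d[2L], d[3L]))
  cls <- array("invalid", c(nw, d[2L], d[3L]))
  for (w in seq_len(nw)) {
    cm <- couple_cells(anom, index, season = season,
                       years = c(starts[w], starts[w] + window - 1L),
                       alpha = alpha, min_n = min_n)
    rho[w, , ] <- cm$rho; p[w, , ] <- cm$p; cls[w, , ] <- cm$class
  }
  structure(list(start_years = starts, rho = rho, p = p, class = cls,
                 window = window, alpha = alpha, season = season),
            class = "window_series")
}

#' Area fraction of a coupling regime
#'
#' Fraction of valid cells in a given regime. The denominator is the number
#' of valid (vegetated) cells, held constant across windows.
#'
#' @param class character matrix or (windows, ny, nx) array of regime labels.
#' @param regime `"deficit"` or `"surplus"` (or `"none"`).
#' @param mask logical validity matrix defining the constant denominator;
#'   default: cells that are not `"invalid"` in (the first window of)
#'   `class`.
#' @return numeric scalar (matrix input) or vector per window (array input).
#' @export
area_fraction <- function(class, regime = c("deficit", "surplus", "none"),
                          mask = NULL) {
  regime <- match.arg(regime)
  if (is.matrix(class)) {
    if (is.null(mask)) mask <- class != "invalid"
    return(sum(class == regime & mask) / sum(mask))
  }
  stopifnot(length(dim(class)) == 3L)
  if (is.null(mask)) mask <- class[1L, , ] != "invalid"
  vapply(seq_len(dim(class)[1L]), function(w) {
    sum(class[w, , ] == regime & mask) / sum(mask)
  }, numeric(1))
}

#' Trend of regime area fractions across moving windows
#'
#' Builds the per-window deficit and surplus area-fraction series from a
#' [moving_windows()] result and tests each for trend, requiring both the
#' linear and the Mann-Kendall test to be significant (the convention used
#' for the headline area trends).
#'
#' @param ws a `window_series` from [moving_windows()].
#' @param mask logical validity matrix (constant denominator).
#' @param alpha significance level.
#' @return list with data.frame `series` (start_year, deficit, surplus,
#'   none) and `trend` (a list of [trend_test()] results per regime).
#' @export
area_fraction_trend <- function(ws, mask = NULL, alpha = 0.05) {
  stopifnot(inherits(ws, "window_series"))
  if (is.null(mask)) mask <- apply(ws$class != "invalid", c(2L, 3L), any)
  ser <- data.frame(
    start_year = ws$start_years,
    deficit = area_fraction(ws$class, "deficit", mask),
    surplus = area_fraction(ws$class, "surplus", mask),
    none = area_fraction(ws$class, "none", mask)
  )
  trends <- list(
    deficit = trend_test(ser$deficit, alpha = alpha, require = "both"),
    surplus = trend_test(ser$surplus, alpha = alpha, require = "both")
  )
  list(series = ser, trend = trends)
}

#' Per-cell trend of the moving-window correlation
#'
#' Tests each cell's window-rho series for trend with [trend_test()].
#'
#' @param ws a `window_series` from [moving_windows()].
#' @param alpha significance level.
#' @param require significance convention (see [trend_test()]); default
#'   `"both"`, matching the mapped coupling-trend screen.
#' @return list of matrices `slope`, `p_linear`, `p_mk` and character matrix
#'   `direction`.
#' @export
window_rho_trend <- function(ws, alpha = 0.05, require = "both") {
  stopifnot(inherits(ws, "window_series"))
  d <- dim(ws$rho)
  slope <- pl <- pm <- matrix(NA_real_, d[2L], d[3L])
  dirn <- matrix(NA_character_, d[2L], d[3L])
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    series <- ws$rho[, iy, ix]
    if (sum(is.finite(series)) < 4L) next
    tr <- trend_test(series, alpha = alpha, require = require)
    slope[iy, ix] <- tr$slope; pl[iy, ix] <- tr$p_linear; pm[iy, ix] <- tr$p_mk
    dirn[iy, ix] <- tr$direction
  }
  list(slope = slope, p_linear = pl, p_mk = pm, direction = dirn)
}
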
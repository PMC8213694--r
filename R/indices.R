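#' Per-cell monthly climatology
#'
#' Computes, for every grid cell and calendar month, the mean and standard
#' deviation of the indicator over a reference period. The standard
#' deviation uses the sample (n - 1) convention; the convention and the
#' reference period are recorded in the returned object so downstream
#' z-scores are reproducible.
#'
#' @param cube a [grid_cube].
#' @param ref_years optional length-2 integer vector (first, last year) of
#'   the reference period; default: the full record.
#' @return object of class `climatology`: list with `mean` and `sd` arrays of
#'   dim (12, ny, nx), `n` (observations per slot), `ref_years`,
#'   `sd_convention = "sample"`.
#' @export
monthly_climatology <- function(cube, ref_years = NULL) {
  stopifnot(inherits(cube, "grid_cube"))
  if (is.null(ref_years)) ref_years <- range(cube$year)
  sel_ref <- cube$year >= ref_years[1L] & cube$year <= ref_years[2L]
  d <- dim(cube$data)
  ncell <- d[2L] * d[3L]
  mu <- sg <- nn <- array(NA_real_, c(12L, d[2L], d[3L]))
  flat <- matrix(cube$data, d[1L], ncell)
  for (m in 1:12) {
    rows <- which(sel_ref & cube$month == m)
    if (length(rows) < 2L)
      stop(sprintf("calendar month %d occurs fewer than twice in the reference period", m))
    X <- flat[rows, , drop = FALSE]
    k <- colSums(is.finite(X))
    s1 <- colSums(X, na.rm = TRUE)
    s2 <- colSums(X^2, na.rm = TRUE)
    mean_m <- ifelse(k > 0, s1 / k, NA_real_)
    var_m <- ifelse(k > 1, pmax(s2 - k * mean_m^2, 0) / (k - 1), NA_real_)
    mu[m, , ] <- mean_m
    sg[m, , ] <- sqrt(var_m)
    nn[m, , ] <- k
  }
  structure(list(mean = mu, sd = sg, n = nn, ref_years = as.integer(ref_years),
                 sd_convention = "sample"),
            class = "climatology")
}

#' Monthly z-score anomalies
#'
#' Standardizes an indicator cube against a per-cell, per-calendar-month
#' climatology: A = (x - monthly mean) / monthly sd. Slots with zero or
#' undefined standard deviation (e.g. a constant series in a cell) are
#' returned as `NA` rather than infinite.
#'
#' @param cube a [grid_cube].
#' @param clim a `climatology` from [monthly_climatology()]; default:
#'   computed from `cube` over its full record.
#' @return a [grid_cube] of anomalies (varname suffixed `"_anom"`).
#' @export
monthly_zscore <- function(cube, clim = NULL) {
  stopifnot(inherits(cube, "grid_cube"))
  if (is.null(clim)) clim <- monthly_climatology(cube)
  if (!inherits(clim, "climatology")) stop("`clim` must be a climatology object")
  d <- dim(cube$data)
  if (!identical(dim(clim$mean)[2:3], d[2:3]))
    stop("climatology grid does not match the cube grid")
  mu <- clim$mean[cube$month, , , drop = FALSE]
  sg <- clim$sd[cube$month, , , drop = FALSE]
  sg[sg <= 0] <- NA_real_
  anom <- (cube$data - mu) / sg
  grid_cube(anom, cube$year[1L], cube$month[1L], mask = cube$mask,
            varname = paste0(cube$varname, "_anom"), units = "z-score")
}

#' Monthly water balance
#'
#' D = precipitation - potential evapotranspiration, elementwise; a month is
#' invalid wherever either input is.
#'
#' @param P,PET aligned precipitation and PET [grid_cube]s (same units).
#' @return a [grid_cube] `D`.
#' @export
water_balance <- function(P, PET) {
  stop_unless_aligned(P, PET, "P and PET")
  grid_cube(P$data - PET$data, P$year[1L], P$month[1L],
            mask = P$mask & PET$mask, varname = "D", units = P$units)
}

#' k-month cumulative aggregation
#'
#' Backward-looking rolling sum: the value at month m is the sum of the k
#' months m-k+1 .. m. The first k-1 months (and any window containing an
#' invalid month) are `NA`.
#'
#' @param D a [grid_cube] of monthly water balance.
#' @param k timescale in months, 1..24.
#' @return a [grid_cube] of k-month sums.
#' @export
aggregate_k <- function(D, k) {
  stopifnot(inherits(D, "grid_cube"))
  k <- as.integer(k)
  if (k < 1L || k > 24L) stop("`k` must be in 1..24")
  d <- dim(D$data)
  flat <- matrix(D$data, d[1L], d[2L] * d[3L])
  agg <- stats::filter(flat, rep(1, k), method = "convolution", sides = 1)
  agg <- matrix(as.numeric(agg), d[1L], d[2L] * d[3L])
  dim(agg) <- d
  grid_cube(agg, D$year[1L], D$month[1L], mask = D$mask,
            varname = sprintf("D%02d", k), units = D$units)
}

#' Aridity classes
#'
#' Partitions the aridity index (mean annual precipitation over mean annual
#' PET) into arid, semi-arid, sub-humid and humid. Boundaries are half-open
#' upward -- [0, 0.2), [0.2, 0.5), [0.5, 0.65), [0.65, Inf) -- so every
#' non-negative AI maps to exactly one class and the upper class wins at a
#' shared boundary. Drylands are the union of the first three classes.
#'
#' @param ai numeric vector/array of aridity-index values, all >= 0.
#' @return factor with levels `c("arid", "semi-arid", "sub-humid", "humid")`
#'   (dimensions of `ai` preserved via `dim` attribute on the integer codes
#'   are not kept; use [aridity_class_matrix()] for gridded input).
#' @export
classify_aridity <- function(ai) {
  if (any(ai < 0, na.rm = TRUE)) stop("aridity index must be >= 0")
  cut(as.numeric(ai), breaks = c(0, 0.2, 0.5, 0.65, Inf), right = FALSE,
      labels = c("arid", "semi-arid", "sub-humid", "humid"))
}

#' Gridded aridity classification
#' @param ai numeric matrix of aridity-index values.
#' @return character matrix of class labels (NA preserved).
#' @export
aridity_class_matrix <- function(ai) {
  out <- as.character(classify_aridity(ai))
  dim(out) <- dim(ai)
  out
}

#' Is a class label a dryland class?
#' @param class character vector of aridity class labels.
#' @return logical.
#' @export
is_dryland <- function(class) class %in% c("arid", "semi-arid", "sub-humid")

#' Drought flags
#'
#' Flags drought months under the two conventions used throughout the
#' package: a 3-month SPEI below -1.28, and an scPDSI-style fixed-timescale
#' index below -1. Both comparisons are strict, so a value exactly at a
#' threshold is not drought.
#'
#' @param spei03 numeric vector/array or [grid_cube] of 3-month SPEI values.
#' @param scpdsi numeric vector/array or [grid_cube] of scPDSI values
#'   (optional).
#' @param spei_threshold,scpdsi_threshold drought thresholds (defaults -1.28
#'   and -1).
#' @return list with logical `drought_spei` (and `drought_scpdsi` if
#'   `scpdsi` supplied), same shape as the inputs (`NA` stays `NA`).
#' @export
flag_drought <- function(spei03, scpdsi = NULL,
                         spei_threshold = -1.28, scpdsi_threshold = -1) {
  take <- function(x) if (inherits(x, "grid_cube")) x$data else x
  out <- list(drought_spei = take(spei03) < spei_threshold)
  if (!is.null(scpdsi)) out$drought_scpdsi <- take(scpdsi) < scpdsi_threshold
  out
}
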
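#' Configuration for the synthetic gridded dataset
#'
#' Bundles and validates every knob of the synthetic world: grid shape and
#' year span, the planted per-cell coupling regime (deficit / surplus /
#' none), the planted SPEI timescale and coupling magnitudes at the start
#' and end of the record (linear drift in between), the planted dominant
#' climate driver, the aridity field, the vegetation noise level, and the
#' seasonal-climate parameters. Scalars are broadcast to the grid; matrices
#' must match it.
#'
#' @param ny,nx grid shape (default 20 x 20).
#' @param start_year,end_year year span (default 1982-2015); at least 10
#'   years are required so moving-window analyses are possible.
#' @param seed integer random seed; every generator stage derives its
#'   stream from it.
#' @param noise_sd standard deviation of the vegetation anomaly noise
#'   (default 0.3).
#' @param regime planted regime per cell: `"deficit"`, `"surplus"` or
#'   `"none"`; scalar or character matrix (ny, nx). Default `"deficit"`.
#' @param timescale planted coupling timescale k in 1..24; scalar or
#'   integer matrix.
#' @param timescale_end optional planted timescale at the end of the
#'   record; when set, the coupling timescale drifts linearly (rounded to
#'   integers) from `timescale` to `timescale_end` over the months, so
#'   windowed response-time analyses have a recoverable trend.
#' @param b_start,b_end planted coupling magnitude (absolute value of the
#'   anomaly loading) at the first and last month; in [0, 1]. Equal values
#'   give stationary coupling; unequal values a linear drift.
#' @param dominant planted dominant driver, one of `"Pre"`, `"Tmp"`,
#'   `"Rad"`, `"CO2"`; scalar or character matrix.
#' @param dominance_snr ratio of the planted low-frequency driver signal to
#'   the driver's window-mean noise (default 2).
#' @param mask_fraction fraction of cells marked invalid
#'   (ocean/unvegetated), default 0.05.
#' @param ai_range range of the aridity-index gradient (default 0.05-1.2,
#'   spanning all four aridity classes).
#' @param clim_base,clim_amplitude,anomaly_scale vegetation seasonal
#'   climatology baseline and amplitude, and the scale with which anomalies
#'   are folded back onto it (raw = climatology + anomaly_scale * A).
#' @param coupling `"direct"` couples the anomaly to the SPEI value at the
#'   planted timescale; `"lagged"` couples it to the standardized water
#'   balance of the single month k-1 months back, which makes the minimum
#'   significant timescale identifiable (see the methods vignette).
#' @param timescale_mode `"nested"` derives all SPEI channels from one
#'   water-balance series (physically consistent); `"independent"` draws
#'   each channel independently (identifiable per-window profiles).
#' @param timescales which SPEI timescales to generate (default 1:24).
#' @param pet_mean,pet_season_amp,pet_noise_sd monthly PET cycle (mm).
#' @param precip_shape gamma shape of monthly precipitation.
#' @param precip_season_amp seasonal modulation of mean precipitation (mm).
#' @param tmp_mean,tmp_season_amp,tmp_noise_sd,tmp_trend air temperature
#'   cycle (degrees C) and linear trend per month.
#' @param rad_mean,rad_season_amp,rad_noise_sd,rad_trend shortwave
#'   radiation cycle (W m-2) and linear trend per month.
#' @param co2_start,co2_drift CO2 series start (ppm) and strictly positive
#'   monthly drift.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(ny = 20L, nx = 20L,
                         start_year = 1982L, end_year = 2015L, seed = 42L,
                         noise_sd = 0.3,
                         regime = "deficit", timescale = 3L,
                         timescale_end = NULL,
                         b_start = 0.5, b_end = 0.5,
                         dominant = "Pre", dominance_snr = 2,
                         mask_fraction = 0.05, ai_range = c(0.05, 1.2),
                         clim_base = 0.5, clim_amplitude = 0.25,
                         anomaly_scale = 0.08,
                         coupling = c("direct", "lagged"),
                         timescale_mode = c("nested", "independent"),
                         timescales = 1:24,
                         pet_mean = 70, pet_season_amp = 50, pet_noise_sd = 5,
                         precip_shape = 4, precip_season_amp = 0.3,
                         tmp_mean = 10, tmp_season_amp = 12,
                         tmp_noise_sd = 1, tmp_trend = 0,
                         rad_mean = 160, rad_season_amp = 80,
                         rad_noise_sd = 8, rad_trend = 0,
                         co2_start = 341, co2_drift = 0.15) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 1L || nx < 1L) stop("grid shape must be at least 1 x 1")
  if (end_year < start_year + 9L)
    stop("need at least 10 years (end_year >= start_year + 9)")
  bcast_chr <- function(v, allowed, what) {
    if (length(v) == 1L) v <- matrix(v, ny, nx)
    v <- as.matrix(v)
    if (!identical(dim(v), c(ny, nx)))
      stop(sprintf("`%s` must be a scalar or a %d x %d matrix", what, ny, nx))
    if (!all(v %in% allowed))
      stop(sprintf("`%s` values must be in {%s}", what, paste(allowed, collapse = ", ")))
    v
  }
  bcast_num <- function(v, what, lo = -Inf, hi = Inf) {
    if (length(v) == 1L) v <- matrix(v, ny, nx)
    v <- as.matrix(v)
    if (!identical(dim(v), c(ny, nx)))
      stop(sprintf("`%s` must be a scalar or a %d x %d matrix", what, ny, nx))
    if (any(v < lo | v > hi, na.rm = TRUE))
      stop(sprintf("`%s` values must lie in [%g, %g]", what, lo, hi))
    v
  }
  regime <- bcast_chr(regime, c("deficit", "surplus", "none"), "regime")
  dominant <- bcast_chr(dominant, DRIVER_ORDER, "dominant")
  timescale <- bcast_num(timescale, "timescale", 1, 24)
  storage.mode(timescale) <- "integer"
  if (!is.null(timescale_end)) {
    timescale_end <- bcast_num(timescale_end, "timescale_end", 1, 24)
    storage.mode(timescale_end) <- "integer"
  }
  b_start <- bcast_num(b_start, "b_start", 0, 1)
  b_end <- bcast_num(b_end, "b_end", 0, 1)
  if (co2_drift <= 0) stop("`co2_drift` must be positive")
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("`mask_fraction` must be in [0, 1)")
  cfg <- list(ny = ny, nx = nx, start_year = as.integer(start_year),
              end_year = as.integer(end_year), seed = as.integer(seed),
              noise_sd = noise_sd, regime = regime, timescale = timescale,
              timescale_end = timescale_end,
              b_start = b_start, b_end = b_end, dominant = dominant,
              dominance_snr = dominance_snr,
              mask_fraction = mask_fraction, ai_range = ai_range,
              clim_base = clim_base, clim_amplitude = clim_amplitude,
              anomaly_scale = anomaly_scale,
              coupling = match.arg(coupling),
              timescale_mode = match.arg(timescale_mode),
              timescales = as.integer(timescales),
              pet_mean = pet_mean, pet_season_amp = pet_season_amp,
              pet_noise_sd = pet_noise_sd, precip_shape = precip_shape,
              precip_season_amp = precip_season_amp,
              tmp_mean = tmp_mean, tmp_season_amp = tmp_season_amp,
              tmp_noise_sd = tmp_noise_sd, tmp_trend = tmp_trend,
              rad_mean = rad_mean, rad_season_amp = rad_season_amp,
              rad_noise_sd = rad_noise_sd, rad_trend = rad_trend,
              co2_start = co2_start, co2_drift = co2_drift)
  needed_k <- unique(as.vector(timescale))
  if (!is.null(timescale_end)) {
    rng <- range(c(timescale, timescale_end))
    needed_k <- seq(rng[1L], rng[2L])   # drift sweeps every intermediate k
  }
  if (!all(needed_k %in% cfg$timescales))
    stop("every planted `timescale` must be among the generated `timescales`")
  structure(cfg, class = "synth_config")
}

#' Static domain: aridity-index field and validity mask
#'
#' Builds a deterministic aridity gradient along x spanning `ai_range`
#' (constant along y) and a seeded random validity mask with
#' `mask_fraction` of the cells marked invalid, emulating ocean or
#' unvegetated ground.
#'
#' @param cfg a [synth_config()].
#' @return list with numeric matrix `ai`, logical matrix `mask`, character
#'   matrix `aridity_class`.
#' @export
make_domain <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  ai <- matrix(rep(seq(cfg$ai_range[1L], cfg$ai_range[2L], length.out = cfg$nx),
                   each = cfg$ny), cfg$ny, cfg$nx)
  set.seed(cfg$seed + 1L)
  mask <- matrix(TRUE, cfg$ny, cfg$nx)
  n_bad <- round(cfg$mask_fraction * length(mask))
  if (n_bad > 0L) mask[sample.int(length(mask), n_bad)] <- FALSE
  list(ai = ai, mask = mask, aridity_class = aridity_class_matrix(ai))
}

## Seasonal shape peaking in July.
.season_cos <- function(month) cos(2 * pi * (month - 7) / 12)

## Centered linear ramp over the record, range 1 (from -0.5 to +0.5).
.ramp <- function(nt) seq(-0.5, 0.5, length.out = nt)

#' Simulate the monthly climate forcing
#'
#' Gamma-distributed precipitation whose seasonal mean tracks the cell's
#' aridity index times the PET cycle (so the long-term P/PET ratio matches
#' the aridity field), a positive seasonal PET cycle, temperature and
#' radiation with seasonal cycles, optional linear trends and noise, and a
#' strictly increasing global CO2 series. Cells where the planted dominant
#' driver is Pre/Tmp/Rad additionally receive a low-frequency linear
#' component in that driver, scaled so its window-mean amplitude is
#' `dominance_snr` times the driver's window-mean noise (the shared latent
#' that attribution must recover); CO2-dominant cells rely on the CO2 ramp
#' itself.
#'
#' @param cfg a [synth_config()].
#' @param domain result of [make_domain()].
#' @param spinup_years extra lead-in years generated before `start_year` so
#'   that k-month aggregations are valid from the first analysis month
#'   (default 2).
#' @return list of [grid_cube]s `pre`, `pet`, `tmp`, `rad` (calendar starts
#'   `start_year - spinup_years`) and numeric vector `co2`.
#' @export
simulate_climate <- function(cfg, domain, spinup_years = 2L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  y0 <- cfg$start_year - as.integer(spinup_years)
  nyrs <- cfg$end_year - y0 + 1L
  nt <- nyrs * 12L
  month <- rep(1:12, nyrs)
  ncell <- cfg$ny * cfg$nx
  sc <- .season_cos(month)
  tt <- seq_len(nt) - 1L

  pet_mu <- pmax(cfg$pet_mean + cfg$pet_season_amp * sc, 1)
  pet <- matrix(pet_mu, nt, ncell) +
    matrix(stats::rnorm(nt * ncell, sd = cfg$pet_noise_sd), nt, ncell)
  pet <- pmax(pet, 1)

  ai_flat <- rep(as.vector(domain$ai), each = nt)
  pre_mu <- pmax(ai_flat * pet_mu * (1 + cfg$precip_season_amp * sc), 2)
  pre <- matrix(stats::rgamma(nt * ncell, shape = cfg$precip_shape,
                              scale = pre_mu / cfg$precip_shape), nt, ncell)

  tmp <- matrix(cfg$tmp_mean + cfg$tmp_season_amp * sc + cfg$tmp_trend * tt,
                nt, ncell) +
    matrix(stats::rnorm(nt * ncell, sd = cfg$tmp_noise_sd), nt, ncell)
  rad <- pmax(matrix(cfg$rad_mean + cfg$rad_season_amp * sc + cfg$rad_trend * tt,
                     nt, ncell) +
                matrix(stats::rnorm(nt * ncell, sd = cfg$rad_noise_sd), nt, ncell), 0)

  ## planted dominance: shared low-frequency ramp in the dominant driver
  ramp <- .ramp(nt)
  ramp_w_sd <- stats::sd(ramp)          # ~ window-mean ramp sd (ramp is smooth)
  n_season <- 35                        # pairs per 5-year window, default layout
  gain <- function(noise_sd)
    cfg$dominance_snr * noise_sd / sqrt(n_season) / ramp_w_sd
  dom_flat <- as.vector(cfg$dominant)
  for (i in seq_len(ncell)) {
    if (dom_flat[i] == "Tmp") tmp[, i] <- tmp[, i] + gain(cfg$tmp_noise_sd) * ramp
    if (dom_flat[i] == "Rad") rad[, i] <- rad[, i] + gain(cfg$rad_noise_sd) * ramp
    if (dom_flat[i] == "Pre") {
      pre_sd <- mean(pre_mu[seq_len(12)]) / sqrt(cfg$precip_shape)
      pre[, i] <- pmax(pre[, i] + gain(pre_sd) * ramp, 0)
    }
  }

  as_cube <- function(m, vn, un) {
    a <- array(m, c(nt, cfg$ny, cfg$nx))
    grid_cube(a, y0, 1L, mask = domain$mask, varname = vn, units = un)
  }
  list(pre = as_cube(pre, "pre", "mm"), pet = as_cube(pet, "pet", "mm"),
       tmp = as_cube(tmp, "tmp", "degC"), rad = as_cube(rad, "rad", "W m-2"),
       co2 = cfg$co2_start + cfg$co2_drift * tt)
}

## Per-calendar-month standardized series of a cube (z-score against its
## own full record), returned as an array like cube$data.
.standardize_monthly <- function(cube) {
  monthly_zscore(cube)$data
}

#' Simulate the vegetation indicator
#'
#' Builds per-cell vegetation anomalies coupled to the water-availability
#' index at the planted timescale -- A(t) = b(t) s(t) + noise_sd eps(t),
#' with b(t) drifting linearly from `b_start` to `b_end`, positive for
#' deficit cells and negative for surplus cells, and pure noise for
#' regime-none cells -- then folds them onto a fixed seasonal climatology:
#' raw = clim_base + clim_amplitude cos(season) + anomaly_scale A.
#' With `coupling = "direct"`, s(t) is the SPEI at the planted timescale;
#' with `"lagged"`, s(t) is the standardized water balance of the single
#' month k-1 months earlier (contained in every aggregation of length >= k,
#' hence identifiable by the minimum-significant-timescale rule).
#'
#' @param cfg a [synth_config()].
#' @param spei_list named list of index cubes per timescale (k-th entry used
#'   for cells planted at timescale k); an absent planted timescale is an
#'   error.
#' @param lag_source for `coupling = "lagged"`: the standardized monthly
#'   water-balance cube (required in that mode).
#' @return list with [grid_cube]s `veg` (raw indicator) and `anomaly` (the
#'   generating anomalies, for direct inspection in tests).
#' @export
simulate_vegetation <- function(cfg, spei_list, lag_source = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3L)
  ref <- spei_list[[1L]]
  if (is.null(ref)) stop("`spei_list` is empty")
  nt <- dim(ref$data)[1L]
  needed <- sort(unique(as.vector(cfg$timescale)))
  if (!is.null(cfg$timescale_end)) {
    rng <- range(c(cfg$timescale, cfg$timescale_end))
    needed <- seq(rng[1L], rng[2L])
  }
  have <- as.integer(sub("\\D*", "", names(spei_list)))
  if (!all(needed %in% have))
    stop(sprintf("SPEI cube(s) missing for planted timescale(s): %s",
                 paste(setdiff(needed, have), collapse = ", ")))
  if (cfg$coupling == "lagged" && is.null(lag_source))
    stop("`lag_source` is required for lagged coupling")
  bseq <- function(b0, b1) seq(b0, b1, length.out = nt)
  A <- array(NA_real_, c(nt, cfg$ny, cfg$nx))
  for (ix in seq_len(cfg$nx)) for (iy in seq_len(cfg$ny)) {
    eps <- stats::rnorm(nt)
    rg <- cfg$regime[iy, ix]
    if (rg == "none") { A[, iy, ix] <- eps; next }
    k <- cfg$timescale[iy, ix]
    s <- if (cfg$coupling == "lagged") {
      x <- lag_source$data[, iy, ix]
      if (k > 1L) c(rep(NA_real_, k - 1L), x[seq_len(nt - k + 1L)]) else x
    } else if (!is.null(cfg$timescale_end)) {
      kt <- round(seq(k, cfg$timescale_end[iy, ix], length.out = nt))
      vapply(seq_len(nt), function(t0)
        spei_list[[match(kt[t0], have)]]$data[t0, iy, ix], numeric(1))
    } else {
      spei_list[[match(k, have)]]$data[, iy, ix]
    }
    b <- bseq(cfg$b_start[iy, ix], cfg$b_end[iy, ix])
    if (rg == "surplus") b <- -b
    A[, iy, ix] <- b * s + cfg$noise_sd * eps
  }
  month <- rep(1:12, length.out = nt)
  clim <- cfg$clim_base + cfg$clim_amplitude * .season_cos(month)
  raw <- clim + cfg$anomaly_scale * A
  dim(raw) <- dim(A)
  list(
    veg = grid_cube(raw, ref$year[1L], ref$month[1L], mask = ref$mask,
                    varname = "veg", units = "index"),
    anomaly = grid_cube(A, ref$year[1L], ref$month[1L], mask = ref$mask,
                        varname = "veg_anom_true", units = "z-score")
  )
}

## Crop a cube to an inclusive year range.
crop_cube <- function(cube, years) {
  sel <- cube$year >= years[1L] & cube$year <= years[2L]
  grid_cube(cube$data[sel, , , drop = FALSE],
            cube$year[sel][1L], cube$month[sel][1L], mask = cube$mask,
            varname = cube$varname, units = cube$units)
}

#' Generate the complete synthetic dataset
#'
#' Runs [make_domain()], [simulate_climate()] (with spin-up so every
#' timescale is valid from the first analysis month), the SPEI stage at the
#' configured timescales (or independent standardized channels in
#' `timescale_mode = "independent"`), and [simulate_vegetation()], cropping
#' everything to `start_year..end_year`. Identical configuration and seed
#' give bit-identical output.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_dataset` with elements `domain` (aridity +
#'   mask), `pre`, `pet`, `tmp`, `rad`, `co2`, `spei` (named list of
#'   cubes), `veg`, `anomaly` and `truth` (a `synth_truth`).
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  domain <- make_domain(cfg)
  clim <- simulate_climate(cfg, domain)
  span <- c(cfg$start_year, cfg$end_year)
  if (cfg$timescale_mode == "independent") {
    set.seed(cfg$seed + 4L)
    nt_full <- dim(clim$pre$data)[1L]
    spei <- lapply(cfg$timescales, function(k) {
      a <- array(stats::rnorm(nt_full * cfg$ny * cfg$nx),
                 c(nt_full, cfg$ny, cfg$nx))
      grid_cube(a, clim$pre$year[1L], 1L, mask = domain$mask,
                varname = sprintf("spei%02d", k), units = "1")
    })
    names(spei) <- sprintf("spei%02d", cfg$timescales)
    lag_src <- NULL
  } else {
    spei <- spei_multiscale(clim$pre, clim$pet, timescales = cfg$timescales,
                            calib_years = span)
    lag_src <- monthly_zscore(water_balance(clim$pre, clim$pet))
  }
  vg <- simulate_vegetation(cfg, spei, lag_source = lag_src)
  sel <- clim$pre$year >= span[1L] & clim$pre$year <= span[2L]
  out <- list(
    domain = domain,
    pre = crop_cube(clim$pre, span), pet = crop_cube(clim$pet, span),
    tmp = crop_cube(clim$tmp, span), rad = crop_cube(clim$rad, span),
    co2 = clim$co2[sel],
    spei = lapply(spei, crop_cube, years = span),
    veg = crop_cube(vg$veg, span), anomaly = crop_cube(vg$anomaly, span),
    truth = structure(list(
      regime = cfg$regime, timescale = cfg$timescale,
      drift_sign = sign(abs(cfg$b_end) - abs(cfg$b_start)),
      dominant = cfg$dominant, seed = cfg$seed,
      coupling = cfg$coupling, timescale_mode = cfg$timescale_mode
    ), class = "synth_truth")
  )
  class(out) <- "synth_dataset"
  out
}

#' Write / read the ground-truth sidecar
#'
#' Serializes the planted truth (regime, timescale, drift sign, dominant
#' driver, seed) to JSON so it can live alongside the NetCDF outputs; the
#' round trip is lossless.
#'
#' @param truth a `synth_truth` (element `truth` of [synth_dataset()]).
#' @param path file path.
#' @return `path` (write) / a `synth_truth` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$timescale <- matrix(as.integer(x$timescale), nrow(x$regime), ncol(x$regime))
  x$drift_sign <- matrix(as.numeric(x$drift_sign), nrow(x$regime), ncol(x$regime))
  x$seed <- as.integer(x$seed)
  structure(x, class = "synth_truth")
}

#' Synthetic drought-response fixture
#'
#' Generates a detrended-anomaly cube plus drought flags in which the mean
#' anomaly of drought-flagged cell-months drifts linearly from 0 at the
#' start of the record to `drift_end` at its end (0 everywhere for the
#' stationary null), with independent Gaussian noise on every cell-month.
#' Drought months are Bernoulli draws at `drought_rate`, the approximate
#' exceedance rate of a standard-normal index below -1.28.
#'
#' @param n_years record length in years (default 34).
#' @param ny,nx grid shape.
#' @param drift_end mean drought-month anomaly at the end of the record
#'   (default -0.5; use 0 for the null).
#' @param noise_sd anomaly noise standard deviation (default 0.3).
#' @param drought_rate fraction of cell-months flagged (default 0.1).
#' @param seed integer seed.
#' @return list with `anom` (a [grid_cube]) and logical array `flags`.
#' @export
simulate_drought_response <- function(n_years = 34L, ny = 5L, nx = 6L,
                                      drift_end = -0.5, noise_sd = 0.3,
                                      drought_rate = 0.1, seed = 1L) {
  set.seed(seed)
  nt <- n_years * 12L
  drift <- seq(0, drift_end, length.out = nt)
  flags <- array(stats::runif(nt * ny * nx) < drought_rate, c(nt, ny, nx))
  A <- array(stats::rnorm(nt * ny * nx, sd = noise_sd), c(nt, ny, nx))
  A <- A + drift * flags          # drift recycles along the time dimension
  list(anom = grid_cube(A, 1982L, 1L, varname = "anom_dt", units = "z-score"),
       flags = flags)
}

#' Synthetic per-cell fixtures for attribution recovery
#'
#' Generates window-level response/driver data directly: for each cell a
#' latent linear component L drives the response (y = L + noise / snr) and
#' the planted dominant driver's column (X_dom = L + noise / snr); the
#' other three columns are independent noise. This is the construction the
#' dominance-recovery tests use, bypassing the climate pipeline so the
#' planted driver is the unique low-frequency covariate.
#'
#' @param ncell number of cells.
#' @param n_windows rows per cell (default 30).
#' @param snr amplitude ratio of the latent to the noise (default 2).
#' @param planted character vector of planted drivers, recycled over cells
#'   (default all four in order).
#' @param seed integer seed.
#' @return list with numeric matrix `y` (n_windows x ncell), array `X`
#'   (n_windows, 4, ncell) and character vector `truth`.
#' @export
simulate_attribution_cells <- function(ncell, n_windows = 30L, snr = 2,
                                       planted = DRIVER_ORDER, seed = 1L) {
  set.seed(seed)
  truth <- rep_len(planted, ncell)
  L <- .ramp(n_windows) / stats::sd(.ramp(n_windows))  # unit-sd latent
  y <- matrix(NA_real_, n_windows, ncell)
  X <- array(NA_real_, c(n_windows, 4L, ncell),
             dimnames = list(NULL, DRIVER_ORDER, NULL))
  for (i in seq_len(ncell)) {
    y[, i] <- L + stats::rnorm(n_windows) / snr
    for (dv in DRIVER_ORDER) {
      X[, dv, i] <- if (dv == truth[i]) L + stats::rnorm(n_windows) / snr
                    else stats::rnorm(n_windows)
    }
  }
  list(y = y, X = X, truth = truth)
}
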
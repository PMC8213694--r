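#' Monthly gridded data cube
#'
#' `grid_cube` is the carrier for every gridded input and intermediate in the
#' package: a 3-D numeric array with dimensions (time, y, x) on a consecutive
#' monthly calendar, together with a static validity mask marking cells that
#' should never enter an analysis (ocean, unvegetated ground). Missing
#' observations within a valid cell are encoded as `NA` in the array itself.
#'
#' @param data numeric array with dim (time, ny, nx). The time dimension must
#'   equal the number of consecutive months implied by the calendar.
#' @param start_year,start_month first month of the record; subsequent time
#'   steps advance one calendar month each.
#' @param mask logical matrix (ny, nx); `TRUE` marks a valid cell. Default:
#'   all valid.
#' @param varname short variable name used when the cube is written to NetCDF.
#' @param units free-text units string carried through I/O.
#'
#' @return an object of class `grid_cube`: a list with elements `data`,
#'   `year`, `month` (integer vectors along time), `mask`, `varname`, `units`.
#' @examples
#' x <- grid_cube(array(rnorm(24 * 2 * 3), c(24, 2, 3)), start_year = 2000)
#' dim(x$data)
#' head(cube_calendar(x))
#' @export
grid_cube <- function(data, start_year, start_month = 1L, mask = NULL,
                      varname = "value", units = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array with dims (time, y, x)")
  nt <- dim(data)[1L]
  if (nt < 1L) stop("cube must contain at least one time step")
  start_month <- as.integer(start_month)
  if (start_month < 1L || start_month > 12L) stop("`start_month` must be in 1..12")
  idx <- seq_len(nt) - 1L
  month <- ((start_month - 1L + idx) %% 12L) + 1L
  year <- as.integer(start_year) + (start_month - 1L + idx) %/% 12L
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(data)[2L], dim(data)[3L])
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(data)[2:3]))
      stop("`mask` dimensions must match the spatial dimensions of `data`")
    storage.mode(mask) <- "logical"
  }
  structure(
    list(data = data, year = year, month = as.integer(month), mask = mask,
         varname = varname, units = units),
    class = "grid_cube"
  )
}

#' @export
print.grid_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grid_cube> %s [%s]: %d months (%d-%02d .. %d-%02d), grid %d x %d, %d/%d valid cells\n",
              x$varname, x$units, d[1L],
              x$year[1L], x$month[1L], x$year[d[1L]], x$month[d[1L]],
              d[2L], d[3L], sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Calendar of a cube
#'
#' @param cube a [grid_cube].
#' @return data.frame with integer columns `year` and `month`, one row per
#'   time step.
#' @export
cube_calendar <- function(cube) {
  stopifnot(inherits(cube, "grid_cube"))
  data.frame(year = cube$year, month = cube$month)
}

#' Number of grid cells and months
#' @param cube a [grid_cube].
#' @return integer vector c(time, ny, nx).
#' @export
cube_dim <- function(cube) dim(cube$data)

## TRUE when two cubes share grid shape and month-by-month calendar.
same_calendar <- function(a, b) {
  identical(dim(a$data)[2:3], dim(b$data)[2:3]) &&
    identical(a$year, b$year) && identical(a$month, b$month)
}

stop_unless_aligned <- function(a, b, what = "cubes") {
  if (!same_calendar(a, b))
    stop(sprintf("%s are not aligned: calendars or grids differ", what))
  invisible(TRUE)
}

## Logical time selector for season months within an inclusive year range.
season_selector <- function(cube, season = 4:10, years = NULL) {
  season <- as.integer(season)
  if (length(season) == 0L || any(season < 1L | season > 12L))
    stop("`season` must be a non-empty subset of 1..12")
  sel <- cube$month %in% season
  if (!is.null(years)) sel <- sel & cube$year >= years[1L] & cube$year <= years[2L]
  sel
}

#' Apply a function over every valid cell of one or more aligned cubes
#'
#' Internal workhorse: iterates over the spatial grid, extracting the time
#' series of each cube at that cell and calling `f(series1, series2, ...)`.
#'
#' @noRd
cell_apply <- function(cubes, f, ...) {
  if (inherits(cubes, "grid_cube")) cubes <- list(cubes)
  ref <- cubes[[1L]]
  d <- dim(ref$data)
  out <- vector("list", d[2L] * d[3L])
  dim(out) <- c(d[2L], d[3L])
  for (ix in seq_len(d[3L])) {
    for (iy in seq_len(d[2L])) {
      if (!ref$mask[iy, ix]) next
      series <- lapply(cubes, function(cb) cb$data[, iy, ix])
      out[[iy, ix]] <- do.call(f, c(series, list(...)))
    }
  }
  out
}

#' Write a cube to NetCDF
#'
#' Writes a CF-style file with 1-D `lat`/`lon` coordinates and a monthly time
#' coordinate encoded as `"months since <first month>-01"`. The validity mask
#' travels as an auxiliary byte variable `mask` so that a write/read
#' round-trip reproduces the cube exactly.
#'
#' @param cube a [grid_cube].
#' @param path output file path.
#' @param lat,lon optional coordinate vectors (lengths ny, nx); defaults are
#'   0.5-degree-spaced grids starting at the origin.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path, lat = NULL, lon = NULL) {
  stopifnot(inherits(cube, "grid_cube"))
  d <- dim(cube$data)
  if (is.null(lat)) lat <- seq(0, by = 0.5, length.out = d[2L])
  if (is.null(lon)) lon <- seq(-180, by = 0.5, length.out = d[3L])
  tunits <- sprintf("months since %d-%02d-01", cube$year[1L], cube$month[1L])
  dim_t <- ncdf4::ncdim_def("time", tunits, seq_len(d[1L]) - 1L,
                            unlim = TRUE, calendar = "standard")
  dim_y <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  dim_x <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  var <- ncdf4::ncvar_def(cube$varname, cube$units, list(dim_x, dim_y, dim_t),
                          missval = 1e30, prec = "double")
  mvar <- ncdf4::ncvar_def("mask", "1", list(dim_x, dim_y), prec = "byte")
  nc <- ncdf4::nc_create(path, list(var, mvar))
  on.exit(ncdf4::nc_close(nc))
  ## internal layout is (time, y, x); NetCDF wants (x, y, time)
  ncdf4::ncvar_put(nc, var, aperm(cube$data, c(3L, 2L, 1L)))
  ncdf4::ncvar_put(nc, mvar, t(cube$mask * 1L))
  invisible(path)
}

#' Read a cube from NetCDF
#'
#' Accepts files written by [write_cube()] and, more generally, any file with
#' a `"months since YYYY-MM-..."` time coordinate advancing one month per
#' step. Non-monthly time steps and non-standard model calendars (e.g.
#' `360_day`) are rejected with an explicit error.
#'
#' @param path NetCDF file path.
#' @param varname variable to read; default: the first non-coordinate,
#'   non-mask variable in the file.
#' @return a [grid_cube].
#' @export
read_cube <- function(path, varname = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vnames <- names(nc$var)
  if (is.null(varname)) {
    cand <- setdiff(vnames, "mask")
    if (length(cand) == 0L) stop("no data variable found in ", path)
    varname <- cand[1L]
  } else if (!varname %in% vnames) {
    stop(sprintf("variable '%s' not found in %s (has: %s)", varname, path,
                 paste(vnames, collapse = ", ")))
  }
  tdim <- nc$dim[["time"]]
  if (is.null(tdim)) stop("file has no 'time' dimension: ", path)
  cal <- if (!is.null(tdim$calendar)) tdim$calendar else "standard"
  if (!cal %in% c("standard", "gregorian", "proleptic_gregorian"))
    stop(sprintf("unsupported calendar '%s' (only standard monthly calendars are handled)", cal))
  m <- regmatches(tdim$units, regexec("^months since ([0-9]{1,4})-([0-9]{1,2})", tdim$units))[[1L]]
  if (length(m) != 3L)
    stop(sprintf("time units '%s' not understood: expected 'months since YYYY-MM-...'", tdim$units))
  steps <- tdim$vals
  if (length(steps) > 1L && any(diff(steps) != 1))
    stop(sprintf("non-monthly time step detected (first offending interval: %s months)",
                 diff(steps)[which(diff(steps) != 1)[1L]]))
  origin_year <- as.integer(m[2L]); origin_month <- as.integer(m[3L])
  off <- origin_month - 1L + as.integer(steps[1L])
  start_year <- origin_year + off %/% 12L
  start_month <- off %% 12L + 1L
  raw <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  data <- aperm(raw, c(3L, 2L, 1L))
  mask <- NULL
  if ("mask" %in% vnames) {
    mk <- ncdf4::ncvar_get(nc, "mask")  # (lon, lat)
    mask <- t(matrix(mk, nrow = dim(data)[3L], ncol = dim(data)[2L])) > 0
  }
  att <- ncdf4::ncatt_get(nc, varname, "units")
  grid_cube(data, start_year, start_month, mask = mask, varname = varname,
            units = if (att$hasatt) att$value else "")
}
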
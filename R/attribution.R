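## Canonical driver order; also the tie-break order for dominance.
DRIVER_ORDER <- c("Pre", "Rad", "Tmp", "CO2")

#' Per-window growing-season driver means
#'
#' Averages each driver over the growing-season months of every moving
#' window, producing the per-cell predictor matrix for the attribution
#' regressions. The CO2 column comes from a global scalar series and is
#' identical across cells.
#'
#' @param pre,tmp,rad aligned [grid_cube]s of precipitation, air temperature
#'   and shortwave radiation.
#' @param co2 numeric monthly series, same length as the cubes' calendar.
#' @param window window length in years.
#' @param season months averaged (default April-October).
#' @return list with `start_years` and `X`, a 4-D array of dim
#'   (n_windows, 4, ny, nx) with driver columns ordered Pre, Tmp, Rad, CO2.
#' @export
window_driver_means <- function(pre, tmp, rad, co2, window = 5L,
                                season = 4:10) {
  stop_unless_aligned(pre, tmp, "precipitation and temperature cubes")
  stop_unless_aligned(pre, rad, "precipitation and radiation cubes")
  if (length(co2) != length(pre$year))
    stop("`co2` must have one value per month of the cubes' calendar")
  yrs <- sort(unique(pre$year))
  window <- as.integer(window)
  starts <- yrs[seq_len(length(yrs) - window + 1L)]
  nw <- length(starts)
  d <- dim(pre$data)
  X <- array(NA_real_, c(nw, 4L, d[2L], d[3L]),
             dimnames = list(NULL, c("Pre", "Tmp", "Rad", "CO2"), NULL, NULL))
  for (w in seq_len(nw)) {
    sel <- season_selector(pre, season, c(starts[w], starts[w] + window - 1L))
    X[w, 1L, , ] <- apply(pre$data[sel, , , drop = FALSE], c(2L, 3L), mean, na.rm = TRUE)
    X[w, 2L, , ] <- apply(tmp$data[sel, , , drop = FALSE], c(2L, 3L), mean, na.rm = TRUE)
    X[w, 3L, , ] <- apply(rad$data[sel, , , drop = FALSE], c(2L, 3L), mean, na.rm = TRUE)
    X[w, 4L, , ] <- mean(co2[sel], na.rm = TRUE)
  }
  list(start_years = starts, X = X)
}

#' Overall F-test of the multivariate driver regression
#'
#' Screens whether the drivers jointly explain the window coupling series:
#' the overall F-test p-value of the linear model y ~ X on raw (unranked)
#' values.
#'
#' @param y numeric response (window rho series).
#' @param X numeric predictor matrix (windows x drivers).
#' @return the model p-value, or `NA` for degenerate inputs (constant y,
#'   too few rows, collinear X).
#' @export
screen_model <- function(y, X) {
  X <- as.matrix(X)
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 2L || stats::var(y) == 0) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < p + 1L) return(NA_real_)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (rss >= tss) return(1)
  Fval <- ((tss - rss) / p) / (rss / (n - p - 1L))
  stats::pf(Fval, p, n - p - 1L, lower.tail = FALSE)
}

## R^2 of y on the columns of X listed in `cols` (empty set -> 0).
.subset_r2 <- function(y, X, cols) {
  if (!length(cols)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Partial Spearman correlation
#'
#' Rank-transforms the response and every predictor column (average ranks
#' for ties), then computes the partial correlation of y with column `j`
#' given the remaining columns. Two algebraically equivalent routes are
#' implemented -- residual-on-residual Pearson correlation after linear fits
#' on the ranks, and the inverse-correlation-matrix identity -- and must
#' agree to numerical precision; the residual route is the default.
#'
#' @param y numeric response.
#' @param X numeric predictor matrix.
#' @param j column index of the driver of interest; `NULL` (default) returns
#'   all columns.
#' @param method `"residual"` or `"matrix"`.
#' @return numeric vector of partial correlations (named when `X` has
#'   column names); `NA` where the conditioning set is collinear.
#' @export
partial_spearman <- function(y, X, j = NULL, method = c("residual", "matrix")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  js <- if (is.null(j)) seq_len(p) else as.integer(j)
  ry <- rank(y)
  RX <- apply(X, 2L, rank)
  out <- rep(NA_real_, length(js))
  names(out) <- colnames(X)[js]
  if (method == "matrix") {
    R <- suppressWarnings(stats::cor(cbind(ry, RX)))
    P <- tryCatch(solve(R), error = function(e) NULL)
    if (!is.null(P)) {
      for (i in seq_along(js)) {
        jj <- js[i] + 1L
        out[i] <- -P[1L, jj] / sqrt(P[1L, 1L] * P[jj, jj])
      }
    }
    return(out)
  }
  for (i in seq_along(js)) {
    jj <- js[i]
    Z <- RX[, -jj, drop = FALSE]
    if (ncol(Z) == 0L) {
      out[i] <- suppressWarnings(stats::cor(ry, RX[, jj]))
      next
    }
    A <- cbind(1, Z)
    f1 <- stats::lm.fit(A, ry)
    f2 <- stats::lm.fit(A, RX[, jj])
    if (stats::var(f2$residuals) <= .Machine$double.eps * stats::var(RX[, jj]) ||
        f1$rank < ncol(A)) next  # collinear conditioning set
    out[i] <- stats::cor(f1$residuals, f2$residuals)
  }
  out
}

#' Dominant driver from partial correlations
#'
#' `none` when the model screen fails (`model_p >= alpha` or `NA`);
#' otherwise the driver with the largest absolute partial correlation. An
#' exact tie is broken by the fixed driver order Pre, Rad, Tmp, CO2 and
#' flagged.
#'
#' @param partials named numeric vector of partial correlations (names from
#'   `Pre`, `Tmp`, `Rad`, `CO2`).
#' @param model_p screening p-value from [screen_model()].
#' @param alpha significance level.
#' @return list with `driver` (character) and `tie` (logical).
#' @export
dominant_factor <- function(partials, model_p, alpha = 0.05) {
  if (!is.finite(model_p) || model_p >= alpha || all(!is.finite(partials)))
    return(list(driver = "none", tie = FALSE))
  av <- abs(partials)
  av[!is.finite(av)] <- -Inf
  mx <- max(av)
  cand <- names(partials)[av == mx]
  if (length(cand) > 1L) {
    ord <- DRIVER_ORDER[DRIVER_ORDER %in% cand]
    return(list(driver = ord[1L], tie = TRUE))
  }
  list(driver = cand, tie = FALSE)
}

#' Exact LMG relative-importance decomposition
#'
#' Decomposes the R^2 of the linear model y ~ X among the predictors by
#' averaging each predictor's sequential R^2 increment over all orderings
#' of the predictors, computed exactly from the 2^p subset R^2 values.
#' Increments are non-negative and the shares sum to the full-model R^2.
#'
#' @param y numeric response.
#' @param X numeric predictor matrix (p columns; exact enumeration, meant
#'   for small p such as the four climate drivers).
#' @return list with `shares` (named numeric, length p), `r2` (full model).
#' @export
lmg_importance <- function(y, X) {
  X <- as.matrix(X)
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  if (length(y) <= p + 2L) stop("need more observations than predictors + 2")
  subsets <- lapply(0:(2^p - 1L), function(b) which(bitwAnd(b, 2^(0:(p - 1L))) > 0))
  r2 <- vapply(subsets, function(s) .subset_r2(y, X, s), numeric(1))
  names(r2) <- vapply(subsets, paste, character(1), collapse = ",")
  key <- function(s) paste(s, collapse = ",")
  shares <- numeric(p)
  fp <- factorial(p)
  for (jj in seq_len(p)) {
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (jj %in% s) next
      wgt <- factorial(length(s)) * factorial(p - 1L - length(s)) / fp
      shares[jj] <- shares[jj] +
        wgt * (r2[[key(sort(c(s, jj)))]] - r2[[i]])
    }
  }
  names(shares) <- colnames(X)
  list(shares = shares, r2 = r2[[key(seq_len(p))]])
}

#' Per-cell attribution of the moving-window coupling series
#'
#' For every valid cell: screens the four-driver regression of the window
#' rho series, computes the partial Spearman correlation of each driver,
#' identifies the dominant driver, and decomposes the model R^2 with
#' [lmg_importance()].
#'
#' @param ws a `window_series` from [moving_windows()].
#' @param drivers result of [window_driver_means()] on the same windows.
#' @param alpha significance level for the model screen.
#' @return object of class `attribution_map`: list with matrices `model_p`,
#'   `r2`, logical `tie`, character `dominant`, and (windows kept per cell)
#'   arrays `partial` and `lmg` of dim (4, ny, nx).
#' @export
attribute_cells <- function(ws, drivers, alpha = 0.05) {
  stopifnot(inherits(ws, "window_series"))
  if (!identical(dim(ws$rho)[1L], dim(drivers$X)[1L]))
    stop("window counts of the coupling series and driver means differ")
  d <- dim(ws$rho)
  model_p <- r2 <- matrix(NA_real_, d[2L], d[3L])
  tie <- matrix(FALSE, d[2L], d[3L])
  dominant <- matrix(NA_character_, d[2L], d[3L])
  partial <- lmg <- array(NA_real_, c(4L, d[2L], d[3L]),
                          dimnames = list(c("Pre", "Tmp", "Rad", "CO2"), NULL, NULL))
  for (ix in seq_len(d[3L])) for (iy in seq_len(d[2L])) {
    y <- ws$rho[, iy, ix]
    X <- drivers$X[, , iy, ix]
    ok <- is.finite(y) & apply(is.finite(X), 1L, all)
    if (sum(ok) < 10L) next
    mp <- screen_model(y, X)
    model_p[iy, ix] <- mp
    pr <- partial_spearman(y, X)
    partial[, iy, ix] <- pr
    dom <- dominant_factor(pr, mp, alpha)
    dominant[iy, ix] <- dom$driver
    tie[iy, ix] <- dom$tie
    li <- tryCatch(lmg_importance(y, X), error = function(e) NULL)
    if (!is.null(li)) { lmg[, iy, ix] <- li$shares; r2[iy, ix] <- li$r2 }
  }
  structure(list(model_p = model_p, r2 = r2, partial = partial, lmg = lmg,
                 dominant = dominant, tie = tie, alpha = alpha),
            class = "attribution_map")
}

#' Dominant-driver area fractions within coupling regimes
#'
#' Within the water-deficit and water-surplus regions, the fraction of
#' significantly explained cells (dominant != none) attributed to each
#' driver. Fractions sum to 1 within a regime; an empty regime gives `NA`s.
#'
#' @param attr an `attribution_map`.
#' @param coupling_class character matrix of full-period regime labels
#'   (from [couple_cells()]).
#' @return matrix (2 x 4): rows `deficit`, `surplus`; columns the drivers.
#' @export
dominant_area_summary <- function(attr, coupling_class) {
  stopifnot(inherits(attr, "attribution_map"))
  out <- matrix(NA_real_, 2L, 4L,
                dimnames = list(c("deficit", "surplus"), DRIVER_ORDER))
  for (rg in rownames(out)) {
    cells <- coupling_class == rg & !is.na(attr$dominant) & attr$dominant != "none"
    tot <- sum(cells, na.rm = TRUE)
    if (tot == 0L) next
    for (dv in DRIVER_ORDER)
      out[rg, dv] <- sum(attr$dominant == dv & cells, na.rm = TRUE) / tot
  }
  out
}
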
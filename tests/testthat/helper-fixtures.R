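# Shared fixtures: small cubes and combinatorial helpers built in code.

toy_cube <- function(nt = 36, ny = 2, nx = 2, start_year = 2000, seed = 1,
                     data = NULL) {
  if (is.null(data)) {
    set.seed(seed)
    data <- array(rnorm(nt * ny * nx), c(nt, ny, nx))
  }
  grid_cube(data, start_year)
}

# All permutations of 1..n as an (n! x n) index matrix.
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Brute-force rank-Pearson correlation (independent of the package path).
rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Mann-Kendall S by definition (explicit pair loop).
mk_S_bruteforce <- function(x) {
  n <- length(x); S <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    S <- S + sign(x[j] - x[i])
  as.integer(S)
}

# A tiny fully-coupled synthetic dataset used by several files.
small_dataset <- function(seed = 7, regime = "deficit", ...) {
  synth_dataset(synth_config(ny = 2, nx = 3, seed = seed, regime = regime,
                             timescales = 1:3, timescale = 3L, ...))
}
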
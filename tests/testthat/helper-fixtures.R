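# Small in-code fixtures shared across the suite.

# Random reflectance spectra on a short 1-nm grid, values safely inside (0, 1).
toy_spectra <- function(n = 4, wl = 400:429, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(n * length(wl), 0.05, 0.95), n, length(wl))
  spectrum_set(v, wl, sprintf("T%02d", seq_len(n)), "R")
}

toy_som <- function(ids, seed = 2) {
  set.seed(seed)
  soil_sample_table(ids, runif(length(ids), 15, 45))
}

# Planted-support benchmark for CARS: p bands of pure noise except n_inf
# bands carrying the standardised SOM signal plus noise at 20% of its sd.
planted_cars_data <- function(seed, n = 120, p = 200, n_inf = 10,
                              noise = 0.2) {
  set.seed(seed)
  y <- rnorm(n, 28.5, 7.8)
  ys <- as.vector(scale(y))
  X <- matrix(rnorm(n * p), n, p)
  informative <- round(seq(10, p - 10, length.out = n_inf))
  for (k in informative) X[, k] <- ys + rnorm(n, 0, noise)
  list(X = X, y = y, informative = informative)
}

# Brute-force upper-hull oracle: hull value at x = max over all chords
# (a, b), x_a <= x <= x_b, of the linear interpolation between points a, b
# (single points included), i.e. the maximum over all piecewise-linear upper
# envelopes through subsets of points.
brute_hull_values <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(q) {
    best <- y[q]
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (x[a] <= x[q] && x[q] <= x[b] && a != b) {
        yy <- y[a] + (y[b] - y[a]) * (x[q] - x[a]) / (x[b] - x[a])
        if (yy > best) best <- yy
      }
    }
    best
  }, numeric(1L))
}

# Scalar loop oracle for the all-pairs index/SOM correlation map.
loop_map_oracle <- function(s, som, kind) {
  p <- length(s$wavelengths_nm)
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j && kind != "DI") next
    v <- pair_index_values(s, s$wavelengths_nm[i], s$wavelengths_nm[j], kind)
    if (anyNA(v) || stats::sd(v) < 1e-14) next
    r[i, j] <- stats::cor(som$som_g_per_kg, v)
  }
  if (kind == "DI") diag(r) <- NA_real_
  r
}

# Independent loop implementation of Kennard-Stone max-min selection.
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(Inf, NA, NA)
  mx <- -Inf
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (D[a, b] > mx) { mx <- D[a, b]; best <- c(a, b) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    md <- vapply(cand, function(q) min(D[q, sel]), numeric(1L))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}
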
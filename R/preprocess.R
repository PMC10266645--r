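#' Savitzky-Golay smoothing
#'
#' Smooths every spectrum with a moving least-squares polynomial filter: at
#' each band the output is the value at the window centre of the polynomial of
#' degree `poly_order` fitted to the `window_bands` surrounding values. Edges
#' are trimmed, not padded: the output grid loses `(window_bands - 1) / 2`
#' bands at each end, so an 11-band window turns a 2151-band spectrum over
#' 350-2500 nm into a 2141-band spectrum over 355-2495 nm. The result carries
#' transform tag `"R"`.
#'
#' @param s a `spectrum_set` on a 1-nm grid (tag `"RAW"` or `"R"`).
#' @param window_bands odd window width in bands (default 11).
#' @param poly_order local polynomial degree (default 2); must be less than
#'   `window_bands`.
#' @return A `spectrum_set` with tag `"R"` on the trimmed grid.
#' @export
savitzky_golay_smooth <- function(s, window_bands = 11L, poly_order = 2L) {
  stopifnot(inherits(s, "spectrum_set"))
  window_bands <- as.integer(window_bands)
  poly_order <- as.integer(poly_order)
  if (window_bands %% 2L == 0L)
    stop("window_bands must be odd", call. = FALSE)
  if (poly_order >= window_bands)
    stop("poly_order must be smaller than window_bands", call. = FALSE)
  p <- length(s$wavelengths_nm)
  if (p < window_bands)
    stop("spectrum has fewer bands than the smoothing window", call. = FALSE)
  half <- (window_bands - 1L) %/% 2L
  # centre row of the SG projection matrix = least-squares smoothing weights
  coefs <- signal::sgolay(p = poly_order, n = window_bands, m = 0)[half + 1L, ]
  n_out <- p - 2L * half
  out <- matrix(0, nrow(s$values), n_out)
  for (k in seq_len(window_bands)) {
    out <- out + coefs[k] * s$values[, k:(k + n_out - 1L), drop = FALSE]
  }
  # smoothing can overshoot [0,1] marginally at sharp features; clamp fp noise
  out[out < 0 & out > -1e-9] <- 0
  out[out > 1 & out < 1 + 1e-9] <- 1
  spectrum_set(out, s$wavelengths_nm[(half + 1L):(p - half)], s$sample_ids, "R")
}

#' Inverse-log reflectance transform
#'
#' Converts reflectance to absorbance-like units: `log10(1 / R)`. This is the
#' usual "inverse-log reflectance" of soil spectroscopy and linearises the
#' approximately exponential darkening of soil with organic matter.
#'
#' @param s a `spectrum_set` with strictly positive values.
#' @return A `spectrum_set` with tag `"LR"`; sample and band order preserved.
#' @export
transform_lr <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  bad <- which(s$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive reflectance at sample '",
         s$sample_ids[bad[1L, 1L]], "', band ",
         s$wavelengths_nm[bad[1L, 2L]], " nm; log10(1/R) undefined",
         call. = FALSE)
  }
  out <- s
  out$values <- log10(1 / s$values)
  out$transform_tag <- "LR"
  colnames(out$values) <- out$wavelengths_nm
  out
}

# Upper convex hull of (x, y) over strictly increasing x, evaluated at every x.
# Andrew's monotone chain, upper chain only; endpoints are always vertices.
upper_hull_values <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- hull[m - 1L]; b <- hull[m]
      # drop b if it lies on or below segment a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) >= 0)
        m <- m - 1L
      else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull <- hull[seq_len(m)]
  stats::approx(x[hull], y[hull], xout = x, method = "linear")$y
}

#' Continuum removal
#'
#' Divides each spectrum by its upper convex hull (the "continuum") anchored
#' at the first and last band, isolating absorption features from the overall
#' albedo. Hull-contact wavelengths, including both endpoints, map to exactly
#' 1; all other values lie in (0, 1].
#'
#' @param s a `spectrum_set` with strictly positive values (at least 2 bands).
#' @return A `spectrum_set` with tag `"CR"`.
#' @export
transform_cr <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (length(s$wavelengths_nm) < 2L)
    stop("continuum removal needs at least 2 bands", call. = FALSE)
  if (any(s$values <= 0))
    stop("continuum removal requires strictly positive reflectance",
         call. = FALSE)
  x <- as.numeric(s$wavelengths_nm)
  out <- s
  out$values <- t(apply(s$values, 1L, function(v) {
    cr <- v / upper_hull_values(x, v)
    cr[cr > 1] <- 1  # fp noise at hull-contact bands
    cr
  }))
  rownames(out$values) <- s$sample_ids
  colnames(out$values) <- s$wavelengths_nm
  out$transform_tag <- "CR"
  out
}

#' First-derivative reflectance
#'
#' Numerical first derivative of reflectance with respect to wavelength
#' (per nm): central differences `(v[i+1] - v[i-1]) / 2` at interior bands and
#' one-sided differences at the two boundary bands, so the band count is
#' preserved and all four representations share one grid.
#'
#' @param s a `spectrum_set` on a 1-nm grid with at least 3 bands.
#' @return A `spectrum_set` with tag `"FDR"`.
#' @export
transform_fdr <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  p <- length(s$wavelengths_nm)
  if (p < 3L)
    stop("derivative needs at least 3 bands", call. = FALSE)
  v <- s$values
  out <- s
  d <- matrix(0, nrow(v), p)
  d[, 2:(p - 1L)] <- (v[, 3:p, drop = FALSE] - v[, 1:(p - 2L), drop = FALSE]) / 2
  d[, 1L] <- v[, 2L] - v[, 1L]
  d[, p] <- v[, p] - v[, p - 1L]
  out$values <- d
  rownames(out$values) <- s$sample_ids
  colnames(out$values) <- s$wavelengths_nm
  out$transform_tag <- "FDR"
  out
}

#' All four spectral representations from a raw spectrum set
#'
#' Convenience wrapper: smooths the raw reflectance, then derives the LR, CR
#' and FDR representations from the smoothed reflectance.
#'
#' @param raw a `spectrum_set` with tag `"RAW"`.
#' @inheritParams savitzky_golay_smooth
#' @return Named list of `spectrum_set`s: `R`, `LR`, `CR`, `FDR`.
#' @export
preprocess_all <- function(raw, window_bands = 11L, poly_order = 2L) {
  r <- savitzky_golay_smooth(raw, window_bands, poly_order)
  list(R = r, LR = transform_lr(r), CR = transform_cr(r),
       FDR = transform_fdr(r))
}
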
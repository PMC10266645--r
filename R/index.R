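#' Deviation of arch (DOA)
#'
#' `DOA = R(600) - (R(550) + R(650)) / 2`, a measure of the visible-range
#' reflectance arch between 550 and 650 nm. The arch flattens as soil organic
#' matter rises, so DOA correlates negatively with SOM.
#'
#' @param s a `spectrum_set` in reflectance units (tag `"R"` or `"RAW"`) whose
#'   grid contains 550, 600 and 650 nm.
#' @return Named numeric vector, one DOA value per sample.
#' @export
deviation_of_arch <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!s$transform_tag %in% c("R", "RAW"))
    stop("DOA is defined on reflectance spectra (tag R or RAW)", call. = FALSE)
  need <- c(550L, 600L, 650L)
  miss <- setdiff(need, s$wavelengths_nm)
  if (length(miss))
    stop("grid is missing band(s) ", paste(miss, collapse = ", "), " nm",
         call. = FALSE)
  i <- match(need, s$wavelengths_nm)
  v <- s$values
  out <- v[, i[2L]] - (v[, i[1L]] + v[, i[3L]]) / 2
  names(out) <- s$sample_ids
  out
}

#' Two-band spectral index values
#'
#' Computes, per sample, the difference index `DI = R_i - R_j`, ratio index
#' `RI = R_i / R_j`, or normalized difference index
#' `NDI = (R_i - R_j) / (R_i + R_j)` from two bands of any spectral
#' representation. RI and NDI values whose denominator has absolute value
#' below 1e-12 are returned as `NA` (invalid) rather than huge numbers.
#'
#' @param s a `spectrum_set`.
#' @param i_nm,j_nm band wavelengths (nm), both on the grid.
#' @param kind `"DI"`, `"RI"` or `"NDI"`.
#' @return Named numeric vector of index values (`NA` marks invalid samples).
#' @export
pair_index_values <- function(s, i_nm, j_nm, kind = c("DI", "RI", "NDI")) {
  stopifnot(inherits(s, "spectrum_set"))
  kind <- match.arg(kind)
  ii <- match(as.integer(i_nm), s$wavelengths_nm)
  jj <- match(as.integer(j_nm), s$wavelengths_nm)
  if (is.na(ii) || is.na(jj))
    stop("band ", if (is.na(ii)) i_nm else j_nm, " nm not on the grid",
         call. = FALSE)
  if (ii == jj && kind != "DI")
    stop(kind, " requires two distinct bands", call. = FALSE)
  ri <- s$values[, ii]
  rj <- s$values[, jj]
  out <- switch(kind,
    DI  = ri - rj,
    RI  = { den <- rj; v <- ri / den; v[abs(den) < 1e-12] <- NA_real_; v },
    NDI = { den <- ri + rj; v <- (ri - rj) / den
            v[abs(den) < 1e-12] <- NA_real_; v })
  names(out) <- s$sample_ids
  out
}

# Correlation of every column of M with y; zero-variance columns -> NA.
cor_with <- function(y, M) {
  yc <- y - mean(y)
  Mc <- sweep(M, 2L, colMeans(M))
  sy <- sqrt(sum(yc^2))
  sm <- sqrt(colSums(Mc^2))
  r <- as.vector(crossprod(yc, Mc)) / (sy * sm)
  r[sm < 1e-14] <- NA_real_
  r
}

#' All-pairs index/SOM correlation map
#'
#' For one index kind and one spectral representation, computes the Pearson
#' correlation between SOM and the index at every ordered band pair (i, j):
#' the surface whose contour plot guides optimal-index selection. Pairs whose
#' index vector has zero variance or contains an invalid value (near-zero
#' denominator) are flagged invalid and excluded from ranking. DI maps are
#' computed in closed form from the band covariance structure; RI/NDI maps by
#' vectorised column sweeps.
#'
#' @param s a `spectrum_set`.
#' @param som a `soil_sample_table` aligned with `s`.
#' @param kind `"DI"`, `"RI"` or `"NDI"`.
#' @param band_stride positive integer; compute the map on every
#'   `band_stride`-th band of the grid (1 = full grid). Coarser strides make
#'   exhaustive search tractable on the 2141-band grid.
#' @return An object of class `index_correlation_map`: list with `kind`,
#'   `transform_tag`, `bands` (wavelengths used), `r_matrix` (rows = band i,
#'   columns = band j; `NA` = invalid) and `n` (sample count).
#' @export
index_correlation_map <- function(s, som, kind = c("DI", "RI", "NDI"),
                                  band_stride = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(s, "spectrum_set"))
  check_aligned(s, som)
  y <- som$som_g_per_kg
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(y) <= 0)
    stop("SOM has zero variance; correlation undefined", call. = FALSE)
  keep <- seq(1L, length(s$wavelengths_nm), by = as.integer(band_stride))
  bands <- s$wavelengths_nm[keep]
  V <- s$values[, keep, drop = FALSE]
  p <- length(bands)
  if (kind == "DI") {
    # r(i,j) = cor(y, V_i - V_j): closed form from band (co)variances
    yc <- y - mean(y)
    Vc <- sweep(V, 2L, colMeans(V))
    cyv <- as.vector(crossprod(yc, Vc))          # sum yc * Vc_k
    Sv <- crossprod(Vc)                          # sum Vc_i Vc_j
    vv <- diag(Sv)
    num <- outer(cyv, cyv, "-")                  # cov num of V_i - V_j with y
    den2 <- outer(vv, vv, "+") - 2 * Sv          # variance num of V_i - V_j
    den2[den2 < 0] <- 0
    r <- num / (sqrt(sum(yc^2)) * sqrt(den2))
    r[den2 < 1e-20] <- NA_real_
  } else {
    r <- matrix(NA_real_, p, p)
    for (j in seq_len(p)) {
      rj <- V[, j]
      if (kind == "RI") {
        den <- matrix(rj, n, p)
        M <- V / den
      } else {
        den <- V + rj
        M <- (V - rj) / den
      }
      bad_col <- colSums(abs(den) < 1e-12) > 0
      rc <- cor_with(y, M)
      rc[bad_col] <- NA_real_
      r[, j] <- rc
    }
    diag(r) <- NA_real_
  }
  dimnames(r) <- list(bands, bands)
  structure(list(kind = kind, transform_tag = s$transform_tag, bands = bands,
                 r_matrix = r, n = n),
            class = "index_correlation_map")
}

#' @export
print.index_correlation_map <- function(x, ...) {
  cat(sprintf("<index_correlation_map> %s on %s spectra, %d bands, n = %d, max |r| = %.3f\n",
              x$kind, x$transform_tag, length(x$bands), x$n,
              max(abs(x$r_matrix), na.rm = TRUE)))
  invisible(x)
}

#' Select the top-correlated spectral indexes from a map
#'
#' Ranks valid map cells by `|r|` descending and returns the top `k` as index
#' definitions. For DI and NDI the mirrored pairs (i, j) and (j, i) carry the
#' same `|r|` (the map is antisymmetric), so they are collapsed to one
#' candidate, canonicalised as `band_i > band_j`; for RI both orderings are
#' genuinely different indexes and remain distinct candidates. Ties in `|r|`
#' are broken toward the lexicographically smaller `(band_i, band_j)`.
#'
#' @param map an `index_correlation_map`.
#' @param k number of indexes to return.
#' @return data.frame with columns `kind`, `transform`, `band_i`, `band_j`,
#'   `r` (signed), ordered by decreasing `|r|`.
#' @export
select_top_indexes <- function(map, k = 1L) {
  stopifnot(inherits(map, "index_correlation_map"), k >= 1L)
  r <- map$r_matrix
  p <- length(map$bands)
  idx <- which(!is.na(r), arr.ind = TRUE)
  if (map$kind %in% c("DI", "NDI")) {
    idx <- idx[idx[, 1L] > idx[, 2L], , drop = FALSE]  # canonical i > j
  } else {
    idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
  }
  if (nrow(idx) < k)
    stop("only ", nrow(idx), " valid candidate cells; k = ", k, call. = FALSE)
  rv <- r[idx]
  bi <- map$bands[idx[, 1L]]
  bj <- map$bands[idx[, 2L]]
  ord <- order(-abs(rv), bi, bj)
  top <- ord[seq_len(k)]
  data.frame(kind = map$kind, transform = map$transform_tag,
             band_i = bi[top], band_j = bj[top], r = rv[top],
             stringsAsFactors = FALSE)
}

#' Assemble the optimal spectral-index feature table
#'
#' Builds the SI-style feature matrix: one DOA column (from the smoothed
#' reflectance) plus, for each of the four representations (R, LR, CR, FDR)
#' and each pair-index kind (DI, RI, NDI), the `k` indexes most correlated
#' with SOM. Column count is therefore `1 + 12 k`: 13 features for `k = 1`
#' (the "SI" set) and 37 for `k = 3` (the "SI3" set).
#'
#' @param spectra named list with `spectrum_set`s `R`, `LR`, `CR`, `FDR`,
#'   mutually aligned and aligned with `som`.
#' @param som a `soil_sample_table`.
#' @param k top-k indexes per (transform, kind).
#' @param band_stride passed to [index_correlation_map()].
#' @param maps optional pre-computed list of maps keyed `"<tag>_<kind>"`
#'   (e.g. `"FDR_NDI"`) to avoid recomputation.
#' @return Numeric matrix (samples x `1 + 12 k`) with an attribute `defs`: a
#'   data.frame of the index definitions (kind, transform, band_i, band_j, r),
#'   one row per column, from which every column can be recomputed with
#'   [compute_index_features()].
#' @export
assemble_si_features <- function(spectra, som, k = 1L, band_stride = 1L,
                                 maps = NULL) {
  need <- c("R", "LR", "CR", "FDR")
  miss <- setdiff(need, names(spectra))
  if (length(miss))
    stop("missing transform(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (tag in need) check_aligned(spectra[[tag]], som)
  defs <- data.frame(kind = "DOA", transform = "R",
                     band_i = NA_integer_, band_j = NA_integer_,
                     r = stats::cor(deviation_of_arch(spectra$R),
                                    som$som_g_per_kg),
                     stringsAsFactors = FALSE)
  for (tag in need) {
    for (kind in c("DI", "RI", "NDI")) {
      key <- paste(tag, kind, sep = "_")
      m <- if (!is.null(maps) && key %in% names(maps)) maps[[key]]
           else index_correlation_map(spectra[[tag]], som, kind, band_stride)
      defs <- rbind(defs, select_top_indexes(m, k))
    }
  }
  X <- compute_index_features(defs, spectra)
  attr(X, "defs") <- defs
  X
}

#' Recompute index feature columns from their definitions
#'
#' @param defs data.frame as produced by [assemble_si_features()] /
#'   [select_top_indexes()].
#' @param spectra named list of `spectrum_set`s (`R`, `LR`, `CR`, `FDR`).
#' @return Numeric matrix, one column per definition row.
#' @export
compute_index_features <- function(defs, spectra) {
  cols <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    if (d$kind == "DOA") return(deviation_of_arch(spectra$R))
    pair_index_values(spectra[[d$transform]], d$band_i, d$band_j, d$kind)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- ifelse(defs$kind == "DOA", "DOA",
                        sprintf("%s_%s(%d,%d)", defs$kind, defs$transform,
                                defs$band_i, defs$band_j))
  X
}

#' Export an index correlation map as a CSV matrix
#'
#' Writes the r-surface with bands as the header row and first column, the
#' layout used to redraw contour maps.
#'
#' @param map an `index_correlation_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_map_csv <- function(map, path) {
  df <- data.frame(band_i = map$bands, map$r_matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
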
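test_that("deviation of arch computes R600 - (R550 + R650)/2", {
  wl <- 500:700
  flat <- spectrum_set(matrix(0.3, 2, length(wl)), wl, c("a", "b"), "R")
  expect_equal(unname(deviation_of_arch(flat)), c(0, 0))

  v <- rep(0.2, length(wl))
  v[wl == 550] <- 0.10; v[wl == 600] <- 0.12; v[wl == 650] <- 0.15
  s <- spectrum_set(rbind(v), wl, "a", "R")
  expect_equal(unname(deviation_of_arch(s)), -0.005)

  trunc <- spectrum_set(matrix(0.3, 1, 50), 560:609, "a", "R")
  expect_error(deviation_of_arch(trunc), "550")
})

test_that("DOA correlates negatively with SOM on arch-flattening spectra", {
  d <- generate_soil_spectra(synthetic_config(n_samples = 150, seed = 21))
  sm <- savitzky_golay_smooth(d$spectra)
  expect_lt(cor(deviation_of_arch(sm), d$som$som_g_per_kg), 0)
})

test_that("pair index identities hold elementwise", {
  s <- toy_spectra(n = 6, wl = 400:419, seed = 4)
  expect_equal(unname(pair_index_values(s, 405, 405, "DI")), rep(0, 6))
  ndi_ij <- pair_index_values(s, 403, 411, "NDI")
  ndi_ji <- pair_index_values(s, 411, 403, "NDI")
  expect_equal(ndi_ij, -ndi_ji)
  ri_ij <- pair_index_values(s, 403, 411, "RI")
  ri_ji <- pair_index_values(s, 411, 403, "RI")
  expect_equal(unname(ri_ij * ri_ji), rep(1, 6))
  expect_error(pair_index_values(s, 405, 405, "RI"), "distinct")
  expect_error(pair_index_values(s, 405, 999, "DI"), "999")
})

test_that("correlation maps match the scalar loop oracle", {
  s <- toy_spectra(n = 12, wl = 700:709, seed = 6)    # 10-band toy
  som <- toy_som(s$sample_ids, seed = 7)
  for (kind in c("DI", "RI", "NDI")) {
    m <- index_correlation_map(s, som, kind)
    oracle <- loop_map_oracle(s, som, kind)
    expect_equal(m$r_matrix, oracle, ignore_attr = TRUE, tolerance = 1e-10)
  }
  # larger instance for the vectorised path
  s2 <- toy_spectra(n = 15, wl = 800:829, seed = 8)
  som2 <- toy_som(s2$sample_ids, seed = 9)
  for (kind in c("DI", "RI", "NDI")) {
    m <- index_correlation_map(s2, som2, kind)
    expect_equal(m$r_matrix, loop_map_oracle(s2, som2, kind),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("maps are bounded, antisymmetric for DI/NDI, and reject degenerate SOM", {
  s <- toy_spectra(n = 10, wl = 500:519, seed = 10)
  som <- toy_som(s$sample_ids, seed = 11)
  for (kind in c("DI", "NDI")) {
    m <- index_correlation_map(s, som, kind)$r_matrix
    expect_true(all(abs(m) <= 1 + 1e-12, na.rm = TRUE))
    expect_equal(m, -t(m), ignore_attr = TRUE, tolerance = 1e-10)
  }
  # Pearson r is invariant to affine rescaling of SOM
  m1 <- index_correlation_map(s, som, "NDI")$r_matrix
  som2 <- soil_sample_table(som$sample_id, 3.7 * som$som_g_per_kg + 11)
  m2 <- index_correlation_map(s, som2, "NDI")$r_matrix
  expect_equal(m1, m2, tolerance = 1e-10)

  const <- soil_sample_table(s$sample_ids, rep(25, 10))
  expect_error(index_correlation_map(s, const, "DI"), "variance")
})

test_that("planted DI pair is the map argmax", {
  set.seed(12)
  s <- toy_spectra(n = 60, wl = 400:429, seed = 12)
  target <- pair_index_values(s, 408, 421, "DI")
  som <- soil_sample_table(
    s$sample_ids, 30 + 10 * as.vector(scale(target)) + rnorm(60, 0, 0.05))
  m <- index_correlation_map(s, som, "DI")
  top <- select_top_indexes(m, 1)
  expect_setequal(c(top$band_i, top$band_j), c(408L, 421L))
})

test_that("top-index selection ranks by |r|, dedups mirrors, keeps RI orderings", {
  s <- toy_spectra(n = 20, wl = 450:455, seed = 13)   # 6-band toy
  som <- toy_som(s$sample_ids, seed = 14)
  for (kind in c("DI", "NDI", "RI")) {
    m <- index_correlation_map(s, som, kind)
    k <- 8L
    top <- select_top_indexes(m, k)
    # exhaustive sort oracle over valid candidate cells
    idx <- which(!is.na(m$r_matrix), arr.ind = TRUE)
    if (kind == "RI") idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    else idx <- idx[idx[, 1] > idx[, 2], , drop = FALSE]
    rv <- m$r_matrix[idx]
    bi <- m$bands[idx[, 1]]; bj <- m$bands[idx[, 2]]
    ord <- order(-abs(rv), bi, bj)[seq_len(k)]
    expect_equal(top$band_i, bi[ord])
    expect_equal(top$band_j, bj[ord])
    expect_equal(top$r, rv[ord])
    # no returned pair is the mirror of another returned pair
    if (kind != "RI") {
      keys <- paste(pmin(top$band_i, top$band_j), pmax(top$band_i, top$band_j))
      expect_false(anyDuplicated(keys) > 0)
    }
  }
  m <- index_correlation_map(s, som, "DI")
  expect_error(select_top_indexes(m, 10000L), "valid candidate")
})

test_that("hand-set map values are ranked like an exhaustive sort", {
  bands <- 450:455
  r <- matrix(NA_real_, 6, 6, dimnames = list(bands, bands))
  vals <- c(0.9, -0.9, 0.5, 0.31, -0.72, 0.11, 0.64, -0.05)
  cells <- rbind(c(2, 1), c(3, 1), c(4, 2), c(5, 3), c(6, 1), c(4, 3),
                 c(5, 2), c(6, 5))
  for (i in seq_along(vals)) {
    r[cells[i, 1], cells[i, 2]] <- vals[i]
    r[cells[i, 2], cells[i, 1]] <- -vals[i]
  }
  m <- structure(list(kind = "DI", transform_tag = "R", bands = bands,
                      r_matrix = r, n = 20),
                 class = "index_correlation_map")
  top <- select_top_indexes(m, 4)
  # |r| ranking: 0.9 (451,450) ties 0.9 (452,450) -> smaller pair first
  expect_equal(top$r, c(0.9, -0.9, -0.72, 0.64))
  expect_equal(top$band_i, c(451L, 452L, 455L, 454L))
  expect_equal(top$band_j, c(450L, 450L, 450L, 451L))
})

test_that("SI feature assembly yields 1 + 12k self-consistent columns", {
  d <- generate_soil_spectra(synthetic_config(n_samples = 40, seed = 15))
  sp <- preprocess_all(d$spectra)
  for (k in c(1L, 3L)) {
    X <- assemble_si_features(sp, d$som, k = k, band_stride = 80L)
    expect_equal(ncol(X), 1L + 12L * k)
    defs <- attr(X, "defs")
    expect_equal(nrow(defs), ncol(X))
    # every column recomputable from its stored definition
    X2 <- compute_index_features(defs, sp)
    expect_equal(X2, X, ignore_attr = TRUE)
  }
  expect_error(assemble_si_features(sp[c("R", "LR")], d$som, 1), "missing")
})
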
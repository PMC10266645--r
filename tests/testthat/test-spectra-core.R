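test_that("spectra table read/write round-trips and validates its format", {
  s <- toy_spectra(n = 2, wl = 350:360)
  raw <- spectrum_set(s$values, s$wavelengths_nm, s$sample_ids, "RAW")
  som <- toy_som(raw$sample_ids)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(raw, som, path)

  rd <- read_spectra_table(path)
  expect_equal(nrow(rd$spectra$values), 2L)
  expect_equal(ncol(rd$spectra$values), 11L)
  expect_identical(rd$spectra$transform_tag, "RAW")
  expect_identical(rd$spectra$values, raw$values)          # bit-for-bit
  expect_identical(rd$som$som_g_per_kg, som$som_g_per_kg)

  # wavelength columns are sorted ascending regardless of file order
  df <- read.csv(path, check.names = FALSE)
  shuffled <- df[, c(1, 2, sample(3:ncol(df)))]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuffled, path2, row.names = FALSE, quote = FALSE)
  rd2 <- read_spectra_table(path2)
  expect_identical(rd2$spectra$wavelengths_nm, rd$spectra$wavelengths_nm)
  expect_equal(rd2$spectra$values, rd$spectra$values)

  # duplicated id is rejected, naming the id
  df_dup <- df
  df_dup$sample_id[2] <- df_dup$sample_id[1]
  write.csv(df_dup, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_spectra_table(path2), df$sample_id[1], fixed = TRUE)

  # percent-scale reflectance is rejected, not rescaled
  df_pct <- df
  df_pct[, 3:ncol(df_pct)] <- df_pct[, 3:ncol(df_pct)] * 100
  write.csv(df_pct, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_spectra_table(path2), "percent")

  # non-integer wavelength header
  df_bad <- df
  names(df_bad)[4] <- "352.5"
  write.csv(df_bad, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_spectra_table(path2), "352.5", fixed = TRUE)
})

test_that("constructors enforce grid, alignment and SOM invariants", {
  expect_error(spectrum_set(matrix(0.5, 1, 3), c(400, 402, 403), "a", "R"),
               "1-nm step")
  expect_error(spectrum_set(matrix(0.5, 2, 3), 400:402, c("a", "a"), "R"),
               "duplicate")
  expect_error(spectrum_set(matrix(1.2, 1, 3), 400:402, "a", "R"),
               "outside")
  expect_error(soil_sample_table(c("a", "b"), c(20, -3)), "> 0")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and trims edges", {
  wl <- 350:2500
  quad <- 1e-8 * (wl - 1200)^2 + 0.2       # degree <= poly_order
  s <- spectrum_set(rbind(quad, 0.9 * quad), wl, c("a", "b"), "RAW")
  sm <- savitzky_golay_smooth(s, 11, 2)

  # 2151 bands over 350-2500 -> 2141 bands over 355-2495
  expect_equal(length(sm$wavelengths_nm), 2141L)
  expect_equal(range(sm$wavelengths_nm), c(355L, 2495L))
  expect_identical(sm$transform_tag, "R")

  quad_out <- 1e-8 * (355:2495 - 1200)^2 + 0.2
  expect_equal(sm$values[1, ], quad_out, ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_error(savitzky_golay_smooth(s, 10), "odd")
  expect_error(savitzky_golay_smooth(toy_spectra(1, 400:404), 11),
               "fewer bands")
})

test_that("each smoothed value equals a direct local polynomial fit", {
  s <- toy_spectra(n = 2, wl = 500:530, seed = 5)     # random 31-band spectrum
  sm <- savitzky_golay_smooth(s, 11, 2)
  for (row in 1:2) {
    for (centre in seq_along(sm$wavelengths_nm)) {
      w <- centre:(centre + 10)                        # window in input bands
      x <- as.numeric(s$wavelengths_nm[w])
      fit <- lm(s$values[row, w] ~ poly(x, 2, raw = TRUE))
      pred <- unname(predict(fit, data.frame(x = x[6])))
      expect_equal(unname(sm$values[row, centre]), pred, tolerance = 1e-10)
    }
  }
})

test_that("inverse-log reflectance is log10(1/R) and refuses non-positive R", {
  s <- spectrum_set(rbind(c(1.0, 0.1, 0.5)), 400:402, "a", "R")
  lr <- transform_lr(s)
  expect_identical(lr$transform_tag, "LR")
  expect_equal(unname(lr$values[1, 1:2]), c(0, 1))
  # monotone inversion: decreasing spectrum -> increasing LR
  dec <- spectrum_set(rbind(seq(0.9, 0.1, length.out = 9)), 400:408, "a", "R")
  expect_true(all(diff(transform_lr(dec)$values[1, ]) > 0))
  # inverse round trip
  back <- 10^(-lr$values)
  expect_equal(back, s$values, tolerance = 1e-12)

  bad <- toy_spectra(1, 400:405)
  bad$values[1, 3] <- 0
  expect_error(transform_lr(bad), "402")
})

test_that("continuum removal divides by the upper convex hull", {
  # affine spectrum equals its own hull -> all 1
  aff <- spectrum_set(rbind(seq(0.2, 0.8, length.out = 21)), 400:420, "a", "R")
  expect_equal(unname(transform_cr(aff)$values[1, ]), rep(1, 21))

  # V-shaped 3-band case
  s3 <- spectrum_set(rbind(c(1.0, 0.5, 1.0)), 400:402, "a", "R")
  expect_equal(unname(transform_cr(s3)$values[1, ]), c(1.0, 0.5, 1.0))

  # random spectra match the brute-force chord-maximum oracle
  s <- toy_spectra(n = 3, wl = 600:611, seed = 9)     # 12 bands
  cr <- transform_cr(s)
  for (row in 1:3) {
    hull <- brute_hull_values(as.numeric(s$wavelengths_nm), s$values[row, ])
    expect_equal(unname(cr$values[row, ]),
                 unname(s$values[row, ] / hull), tolerance = 1e-10)
  }
  # endpoints are hull contacts; everything in (0, 1]
  expect_equal(unname(cr$values[, 1]), rep(1, 3))
  expect_equal(unname(cr$values[, 12]), rep(1, 3))
  expect_true(all(cr$values > 0 & cr$values <= 1))
  expect_error(transform_cr(toy_spectra(1, 400:400)), "2 bands")
})

test_that("first-derivative reflectance uses central differences, keeps bands", {
  const <- spectrum_set(matrix(0.4, 2, 9), 400:408, c("a", "b"), "R")
  expect_true(all(transform_fdr(const)$values == 0))

  m <- 5e-4
  aff <- spectrum_set(rbind(0.2 + m * (0:20)), 400:420, "a", "R")
  expect_equal(unname(transform_fdr(aff)$values[1, ]), rep(m, 21))

  # sinusoid of period 200 nm vs analytic derivative
  wl <- 400:999
  amp <- 0.2
  v <- 0.5 + amp * sin(2 * pi * wl / 200)
  s <- spectrum_set(rbind(v), wl, "a", "R")
  d <- transform_fdr(s)
  analytic <- amp * (2 * pi / 200) * cos(2 * pi * wl / 200)
  expect_equal(length(d$wavelengths_nm), length(wl))  # band count preserved
  expect_lt(max(abs(d$values[1, ] - analytic)), 1e-3 * amp)

  # derivative of a cumulative sum recovers the summand at interior bands
  set.seed(3)
  inc <- runif(30, 0, 0.01)
  cum <- spectrum_set(rbind(0.1 + cumsum(inc)), 500:529, "a", "R")
  rec <- transform_fdr(cum)$values[1, 2:29]
  mid <- (inc[2:29] + inc[3:30]) / 2                  # central-diff target
  expect_equal(unname(rec), mid, tolerance = 1e-12)

  expect_error(transform_fdr(toy_spectra(1, 400:401)), "3 bands")
})

test_that("all transforms preserve sample order and count", {
  s <- toy_spectra(n = 5, wl = 420:460, seed = 11)
  for (f in list(transform_lr, transform_cr, transform_fdr)) {
    out <- f(s)
    expect_identical(out$sample_ids, s$sample_ids)
    expect_equal(nrow(out$values), 5L)
  }
  sm <- savitzky_golay_smooth(s)
  expect_identical(sm$sample_ids, s$sample_ids)
})
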
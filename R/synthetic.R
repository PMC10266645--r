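#' Synthetic soil-spectra configuration
#'
#' Study conditions for the generator: a 178-sample survey with SOM averaging
#' 28.54 +/- 7.80 g/kg over 11.85-58.22 g/kg, VNIR spectra on the 350-2500 nm
#' 1-nm grid (2151 bands before smoothing) that darken monotonically with SOM
#' across the whole range (strongest over 400-900 nm), a visible-range
#' 550-650 nm arch that flattens as SOM rises (so DOA correlates
#' negatively), and water/clay absorption features near 1400, 1900 and
#' 2200 nm with per-sample random depths independent of SOM.
#'
#' Two nuisance terms bound the attainable prediction accuracy.
#' `baseline_jitter_sd` is a per-sample multiplicative albedo jitter
#' (log-normal sd) emulating particle-size and moisture variation.
#' `chromophore_sd` (g/kg) is error in the link between measured SOM and the
#' optically active chromophore pool that actually darkens the spectrum
#' (wet-chemistry assay error plus non-SOM chromophores such as iron oxides);
#' because it perturbs the darkening itself, no amount of spectral averaging
#' removes it, and it caps validation R2 near
#' `1 - chromophore_sd^2 / som_sd^2`. The default 2 g/kg puts PLS validation
#' R2 near 0.85 after the Kennard-Stone split (whose validation half has
#' smaller SOM spread than the survey).
#'
#' @param n_samples number of soil samples.
#' @param som_mean,som_sd,som_min,som_max truncated-normal SOM parameters
#'   (g/kg).
#' @param features list of absorption features, each
#'   `c(center_nm, width_nm, depth_min, depth_max)`.
#' @param beta0 baseline darkening coefficient (per g/kg), all wavelengths.
#' @param beta_vis extra visible-range darkening amplitude (per g/kg),
#'   Gaussian in wavelength around 650 nm (width 300 nm).
#' @param arch_gain relative amplitude of the 600-nm arch at the lowest SOM
#'   (decays linearly to 0 at `som_max`).
#' @param baseline_jitter_sd per-sample multiplicative albedo jitter (sd of
#'   log reflectance).
#' @param chromophore_sd sd (g/kg) of the error between measured SOM and the
#'   darkening chromophore pool.
#' @param noise_sd additive band noise (reflectance units).
#' @param planted_pair optional list `(kind, band_i, band_j, target_r)` for
#'   [generate_planted_index_data()].
#' @param seed RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 178L, som_mean = 28.54,
                             som_sd = 7.80, som_min = 11.85, som_max = 58.22,
                             features = list(c(1400, 30, 0.05, 0.12),
                                             c(1900, 45, 0.10, 0.20),
                                             c(2200, 28, 0.04, 0.09)),
                             beta0 = 0.006, beta_vis = 0.006,
                             arch_gain = 0.08, baseline_jitter_sd = 0.06,
                             chromophore_sd = 2.0, noise_sd = 0.004,
                             planted_pair = NULL, seed = 1L) {
  if (!(som_min < som_mean && som_mean < som_max))
    stop("need som_min < som_mean < som_max", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  centers <- vapply(features, `[`, numeric(1L), 1L)
  if (any(centers < 350 | centers > 2500))
    stop("absorption feature centers must lie in 350-2500 nm", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), som_mean = som_mean,
                 som_sd = som_sd, som_min = som_min, som_max = som_max,
                 features = features, beta0 = beta0, beta_vis = beta_vis,
                 arch_gain = arch_gain,
                 baseline_jitter_sd = baseline_jitter_sd,
                 chromophore_sd = chromophore_sd,
                 noise_sd = noise_sd, planted_pair = planted_pair,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling of the truncated normal
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate soil-like VNIR spectra with known SOM dependence
#'
#' Per-sample reflectance over 350-2500 nm (1-nm grid, 2151 bands) is built
#' as: smooth sigmoidal baseline rising through the visible and plateauing in
#' the NIR, times an SOM-dependent arch near 600 nm that flattens as SOM
#' rises, times Gaussian absorption features (random per-sample depths),
#' times exponential darkening `exp(-beta(lambda) * SOM)` with `beta`
#' largest over 400-900 nm, times a per-sample albedo jitter, plus additive
#' band noise; finally clipped to (0.001, 1). SOM is drawn from a truncated
#' normal.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `spectra` (`spectrum_set`, tag `"RAW"`) and `som`
#'   (`soil_sample_table`).
#' @export
generate_soil_spectra <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  out <- generate_spectra_impl(cfg)
  list(spectra = out$spectra, som = out$som)
}

generate_spectra_impl <- function(cfg) {
  n <- cfg$n_samples
  wl <- 350:2500
  p <- length(wl)
  som <- rtruncnorm1(n, cfg$som_mean, cfg$som_sd, cfg$som_min, cfg$som_max)
  # the optically active chromophore pool tracks measured SOM with error
  chrom <- som + stats::rnorm(n, 0, cfg$chromophore_sd)
  chrom <- pmax(chrom, 0.1)
  ids <- sprintf("S%03d", seq_len(n))

  baseline <- 0.15 + 0.45 / (1 + exp(-(wl - 700) / 250))
  beta <- cfg$beta0 + cfg$beta_vis * exp(-((wl - 650) / 300)^2)
  arch_shape <- exp(-((wl - 600) / 45)^2)
  # arch amplitude decays linearly with SOM: flat curve for SOM-rich soil
  arch_amp <- cfg$arch_gain *
    pmax(0, (cfg$som_max - chrom) / (cfg$som_max - cfg$som_min))

  V <- matrix(baseline, n, p, byrow = TRUE)
  V <- V * (1 + outer(arch_amp, arch_shape))
  for (f in cfg$features) {
    depth <- stats::runif(n, f[3L], f[4L])
    V <- V * (1 - outer(depth, exp(-((wl - f[1L]) / f[2L])^2 / 2)))
  }
  V <- V * exp(-outer(chrom, beta))
  if (cfg$baseline_jitter_sd > 0)
    V <- V * exp(stats::rnorm(n, 0, cfg$baseline_jitter_sd))
  if (cfg$noise_sd > 0)
    V <- V + matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  V <- pmin(pmax(V, 0.001), 1)
  list(spectra = spectrum_set(V, wl, ids, "RAW"),
       som = soil_sample_table(ids, som), som_values = som)
}

#' Generate spectra with a planted optimal index pair
#'
#' Generates spectra as [generate_soil_spectra()] does, then re-derives SOM
#' as a linear function of the planted two-band index computed from those
#' spectra, plus calibrated Gaussian noise, so that the Pearson correlation
#' between SOM and the planted index hits `target_r` (up to sampling error;
#' within about +/- 0.05 at n >= 150). The planted pair should then be the
#' argmax (up to band collinearity) of the corresponding correlation map.
#'
#' SOM is rescaled to the configured mean/sd but not truncated, so the
#' planted correlation is not distorted.
#'
#' @param cfg a [synthetic_config()] with `planted_pair` set: a list with
#'   `kind` (`"DI"`, `"RI"`, `"NDI"`), `band_i`, `band_j` (nm on the grid)
#'   and `target_r` in `[0, 0.999]` (the target |r|).
#' @return List with `spectra`, `som`, `pair` (the ground-truth definition)
#'   and `achieved_r` (empirical correlation in this draw).
#' @export
generate_planted_index_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pp <- cfg$planted_pair
  if (is.null(pp)) stop("cfg$planted_pair is not set", call. = FALSE)
  target <- abs(pp$target_r)
  if (target > 0.999)
    stop("target |r| above the achievable bound 0.999", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  gen <- generate_spectra_impl(cfg)
  s <- gen$spectra
  if (!all(c(pp$band_i, pp$band_j) %in% s$wavelengths_nm))
    stop("planted bands not on the grid", call. = FALSE)
  z <- pair_index_values(s, pp$band_i, pp$band_j, pp$kind)
  zs <- as.vector(scale(z))
  n <- cfg$n_samples
  w <- if (target == 0) stats::rnorm(n)
       else target * zs + sqrt(1 - target^2) * stats::rnorm(n)
  som <- cfg$som_mean + cfg$som_sd * as.vector(scale(w))
  som <- pmax(som, 0.01)  # SOM must stay positive
  list(spectra = s,
       som = soil_sample_table(s$sample_ids, som),
       pair = pp,
       achieved_r = stats::cor(som, z))
}
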
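#' CARS configuration
#'
#' Settings for competitive adaptive reweighted sampling. Defaults follow
#' common usage of the algorithm: 50 Monte Carlo runs, 80% of calibration
#' samples drawn per run, 10-fold RMSECV, at most 10 latent variables.
#'
#' @param n_runs number of Monte Carlo sampling runs (>= 2).
#' @param mc_sample_ratio fraction of calibration samples drawn (0, 1).
#' @param cv_folds folds for the RMSECV of each retained subset (>= 2).
#' @param max_pls_components cap on PLS latent variables (>= 1).
#' @param inner_cv_folds folds of the per-run component-selection CV.
#' @param seed integer random seed; fixes the whole trajectory.
#' @return A list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50L, mc_sample_ratio = 0.8, cv_folds = 10L,
                        max_pls_components = 10L, inner_cv_folds = 5L,
                        seed = 1L) {
  stopifnot(n_runs >= 2L, mc_sample_ratio > 0, mc_sample_ratio < 1,
            cv_folds >= 2L, max_pls_components >= 1L, inner_cv_folds >= 2L)
  structure(list(n_runs = as.integer(n_runs),
                 mc_sample_ratio = mc_sample_ratio,
                 cv_folds = as.integer(cv_folds),
                 max_pls_components = as.integer(max_pls_components),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed)),
            class = "cars_config")
}

#' Exponential damping function retention ratio
#'
#' The forced-selection schedule of CARS: the fraction of the original bands
#' retained at run `i` decays exponentially, `a * exp(-k * i)`, with the
#' boundary conditions ratio(1) = 1 (all bands) and ratio(N) = 2/p (two
#' bands), giving `k = log(p / 2) / (N - 1)` and `a = exp(k)`.
#'
#' @param i run index (1..`n_runs`), vectorised.
#' @param n_runs total number of runs N (>= 2).
#' @param n_bands number of original bands p (>= 2).
#' @return Retention ratio(s) in (0, 1].
#' @export
edf_ratio <- function(i, n_runs, n_bands) {
  if (n_bands < 2L) stop("need at least 2 bands", call. = FALSE)
  if (n_runs < 2L) stop("need at least 2 runs", call. = FALSE)
  k <- log(n_bands / 2) / (n_runs - 1)
  a <- exp(k)
  a * exp(-k * i)
}

#' Competitive adaptive reweighted sampling
#'
#' Selects characteristic bands by competition between PLS regression
#' coefficients. Each Monte Carlo run: (a) draws a random subset of
#' calibration samples; (b) fits a PLS model on the currently retained bands
#' (latent variables chosen by inner cross-validation, capped); (c) weights
#' each band by the absolute value of its regression coefficient; (d) applies
#' forced selection, keeping the top bands by weight down to the exponential
#' damping ratio of that run; (e) applies adaptive reweighted sampling,
#' drawing bands with probability proportional to weight (with replacement)
#' and retaining the distinct picks; and (f) scores the retained subset by
#' K-fold cross-validated RMSE over all calibration samples. The subset with
#' the minimum RMSECV wins (earliest run on ties).
#'
#' If the retained set collapses below 2 bands before the final run, the
#' remaining runs are recorded as failures, traces are truncated, and the
#' best subset is taken over completed runs.
#'
#' @param X numeric matrix (samples x bands), calibration predictors.
#' @param y SOM vector (g/kg), aligned with `X`.
#' @param cfg a [cars_config()].
#' @param wavelengths_nm optional band labels (defaults to column names or
#'   column index).
#' @return An object of class `cars_result`: list with
#'   `retained_ratio_trace`, `subset_trace` (list of retained band index
#'   sets), `rmsecv_trace` (g/kg), `ncomp_trace`, `best_run`,
#'   `best_bands_nm`, `best_band_idx`, `best_rmsecv`, `n_runs_completed`,
#'   `wavelengths_nm`, `config`.
#' @export
run_cars <- function(X, y, cfg = cars_config(), wavelengths_nm = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (p < 3L) stop("CARS needs at least 3 bands", call. = FALSE)
  if (n < cfg$cv_folds) stop("fewer samples than cv_folds", call. = FALSE)
  if (is.null(wavelengths_nm)) {
    wavelengths_nm <- suppressWarnings(as.numeric(colnames(X)))
    if (is.null(colnames(X)) || anyNA(wavelengths_nm))
      wavelengths_nm <- seq_len(p)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  n_mc <- ceiling(cfg$mc_sample_ratio * n)
  retained <- seq_len(p)
  ratio_trace <- numeric(0)
  subset_trace <- list()
  rmsecv_trace <- numeric(0)
  ncomp_trace <- integer(0)

  for (i in seq_len(cfg$n_runs)) {
    if (length(retained) < 2L) break
    mc <- sample.int(n, n_mc)
    Xi <- X[mc, retained, drop = FALSE]
    yi <- y[mc]
    # component count by inner CV on the Monte Carlo subsample
    inner <- pls_cv_rmse(Xi, yi, ncomp_max = cfg$max_pls_components,
                         folds = cfg$inner_cv_folds)
    fit <- simpls_fit(Xi, yi, inner$best_ncomp)
    w <- abs(fit$coef[, fit$ncomp])
    # (d) forced selection by the damping schedule (ratio of original p)
    n_keep <- min(length(retained), ceiling(edf_ratio(i, cfg$n_runs, p) * p))
    keep <- order(w, decreasing = TRUE)[seq_len(n_keep)]
    retained <- retained[keep]
    w <- w[keep]
    # (e) adaptive reweighted sampling: weighted draws with replacement
    if (sum(w) <= 0) break
    picks <- sample.int(length(retained), length(retained), replace = TRUE,
                        prob = w)
    retained <- sort(retained[unique(picks)])
    if (length(retained) < 2L) break
    # (f) RMSECV of the retained subset over all calibration samples
    cv <- pls_cv_rmse(X[, retained, drop = FALSE], y,
                      ncomp_max = cfg$max_pls_components,
                      folds = cfg$cv_folds)
    ratio_trace <- c(ratio_trace, edf_ratio(i, cfg$n_runs, p))
    subset_trace[[length(subset_trace) + 1L]] <- retained
    rmsecv_trace <- c(rmsecv_trace, cv$best_rmse)
    ncomp_trace <- c(ncomp_trace, cv$best_ncomp)
  }
  if (!length(rmsecv_trace))
    stop("CARS failed: retained set collapsed before any run completed",
         call. = FALSE)
  best <- which.min(rmsecv_trace)  # first minimum on ties
  structure(list(retained_ratio_trace = ratio_trace,
                 subset_trace = subset_trace,
                 rmsecv_trace = rmsecv_trace,
                 ncomp_trace = ncomp_trace,
                 best_run = best,
                 best_band_idx = subset_trace[[best]],
                 best_bands_nm = wavelengths_nm[subset_trace[[best]]],
                 best_rmsecv = rmsecv_trace[best],
                 n_runs_completed = length(rmsecv_trace),
                 wavelengths_nm = wavelengths_nm,
                 config = cfg),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(paste0("<cars_result> %d/%d runs completed; best run %d: ",
                     "%d bands, RMSECV = %.3f g/kg\n"),
              x$n_runs_completed, x$config$n_runs, x$best_run,
              length(x$best_band_idx), x$best_rmsecv))
  invisible(x)
}

#' Export a CARS result
#'
#' Writes a CSV of band selection (`wavelength_nm`, `selected` 0/1 for the
#' best subset) and a JSON trace (retention ratios, RMSECV and subset size
#' per run) sufficient to redraw the selection trajectory.
#'
#' @param res a `cars_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_cars_result <- function(res, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(wavelength_nm = res$wavelengths_nm,
                 selected = as.integer(seq_along(res$wavelengths_nm) %in%
                                         res$best_band_idx)),
      csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(retained_ratio = res$retained_ratio_trace,
           rmsecv = res$rmsecv_trace,
           subset_size = vapply(res$subset_trace, length, 1L),
           best_run = res$best_run,
           best_bands_nm = res$best_bands_nm),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
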
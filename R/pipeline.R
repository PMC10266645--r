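#' Full-pipeline run configuration
#'
#' Bundles every setting of the end-to-end workflow: data source (a spectra
#' file or a synthetic configuration), preprocessing, index search, CARS,
#' the Kennard-Stone split fraction, the model list and the seed.
#'
#' `selection_mode` controls an information-leakage trade-off: `"paper"`
#' selects optimal indexes and CARS bands on all samples (the convention of
#' correlation-map studies, where the map is drawn on the full survey);
#' `"strict"` restricts both selections to the calibration set. The chosen
#' mode is recorded in the report provenance.
#'
#' @param input_path path to a wide spectra table, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] (used when `input_path` is NULL).
#' @param routes feature routes to run, subset of
#'   `c("SI", "SI3", "full", "CARS")`.
#' @param models named list of [model_spec()]s.
#' @param transforms spectral representations for the full-spectrum and CARS
#'   routes.
#' @param cal_fraction calibration fraction for the Kennard-Stone split
#'   (default 133/178).
#' @param index_band_stride,cars_band_stride band strides for the index maps
#'   and the CARS input (1 = full grid).
#' @param si_k,si3_k top-k per (transform, kind) for the SI and SI3 sets.
#' @param cars a [cars_config()].
#' @param selection_mode `"paper"` (select on all samples) or `"strict"`
#'   (calibration only).
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   offset scheme so single stages re-run reproducibly.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_path = NULL, synthetic = synthetic_config(),
                       routes = c("SI", "SI3", "CARS"),
                       models = list(SVR = model_spec("SVR"),
                                     PLSR = model_spec("PLSR")),
                       transforms = c("R", "LR", "CR", "FDR"),
                       cal_fraction = 133 / 178,
                       index_band_stride = 10L, cars_band_stride = 5L,
                       si_k = 1L, si3_k = 3L,
                       cars = cars_config(),
                       selection_mode = c("paper", "strict"),
                       seed = 1L) {
  if (!length(routes) || !length(models))
    stop("enable at least one route and one model", call. = FALSE)
  routes <- match.arg(routes, c("SI", "SI3", "full", "CARS"),
                      several.ok = TRUE)
  selection_mode <- match.arg(selection_mode)
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop("cal_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(input_path = input_path, synthetic = synthetic,
                 routes = routes, models = models, transforms = transforms,
                 cal_fraction = cal_fraction,
                 index_band_stride = as.integer(index_band_stride),
                 cars_band_stride = as.integer(cars_band_stride),
                 si_k = as.integer(si_k), si3_k = as.integer(si3_k),
                 cars = cars, selection_mode = selection_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

# fixed fan-out of the global seed to stage seeds (kept < 2^31; double
# arithmetic avoids integer overflow for large seeds)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, split = 202, cars = 303, model = 404)
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

subset_spectra <- function(s, idx) {
  spectrum_set(s$values[idx, , drop = FALSE], s$wavelengths_nm,
               s$sample_ids[idx], s$transform_tag)
}

#' Run the full SOM modeling workflow
#'
#' Executes: data loading or simulation; Savitzky-Golay smoothing and the
#' LR/CR/FDR transforms; optimal-index search and SI/SI3 assembly; CARS band
#' selection per transform; the Kennard-Stone split on the smoothed
#' reflectance; then, for every enabled feature route x model, grid-searched
#' fitting and evaluation. Stages log to `message()` with timings.
#'
#' @param cfg a [run_config()].
#' @return List of class `report_bundle`: `evaluations` (one data.frame row
#'   per route/transform/model with R2/RMSE for both sets, RPD, LCCC),
#'   `index_defs` (SI/SI3 definitions), `cars_bands` (selected wavelengths
#'   per transform), `split`, `reports` (the raw `eval_report`s),
#'   `provenance`.
#' @export
run_full_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    message(sprintf("[somspec %7.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  }

  if (!is.null(cfg$input_path)) {
    log_stage("reading %s", cfg$input_path)
    dat <- read_spectra_table(cfg$input_path)
  } else {
    sim_cfg <- cfg$synthetic
    sim_cfg$seed <- stage_seed(cfg$seed, "simulate")
    log_stage("simulating %d samples (seed %d)", sim_cfg$n_samples,
              sim_cfg$seed)
    dat <- generate_soil_spectra(sim_cfg)
  }
  som <- dat$som

  log_stage("preprocessing: SG smoothing + LR/CR/FDR")
  spectra <- preprocess_all(dat$spectra)

  n <- length(som$sample_id)
  n_cal <- round(cfg$cal_fraction * n)
  split <- kennard_stone_split(spectra$R$values, n_cal,
                               sample_ids = som$sample_id)
  log_stage("Kennard-Stone split: %d calibration / %d validation",
            length(split$calibration_idx), length(split$validation_idx))

  sel_idx <- if (cfg$selection_mode == "strict") split$calibration_idx
             else seq_len(n)
  sel_spectra <- lapply(spectra, subset_spectra, idx = sel_idx)
  sel_som <- soil_sample_table(som$sample_id[sel_idx],
                               som$som_g_per_kg[sel_idx])

  y <- som$som_g_per_kg
  cal <- split$calibration_idx; val <- split$validation_idx

  feature_sets <- list()   # route -> list(tag -> feature matrix over all samples)
  index_defs <- NULL
  if (any(c("SI", "SI3") %in% cfg$routes)) {
    for (route in intersect(c("SI", "SI3"), cfg$routes)) {
      k <- if (route == "SI") cfg$si_k else cfg$si3_k
      log_stage("index search (%s, k = %d, stride %d)", route, k,
                cfg$index_band_stride)
      Xsel <- assemble_si_features(sel_spectra, sel_som, k = k,
                                   band_stride = cfg$index_band_stride)
      defs <- attr(Xsel, "defs")
      X <- compute_index_features(defs, spectra)
      defs$route <- route
      index_defs <- rbind(index_defs, defs)
      feature_sets[[route]] <- list(index = X)
    }
  }
  if ("full" %in% cfg$routes) {
    feature_sets$full <- lapply(spectra[cfg$transforms],
                                function(s) s$values)
  }
  cars_bands <- list()
  if ("CARS" %in% cfg$routes) {
    feats <- list()
    for (tag in cfg$transforms) {
      s <- sel_spectra[[tag]]
      keep <- seq(1L, length(s$wavelengths_nm), by = cfg$cars_band_stride)
      ccfg <- cfg$cars
      ccfg$seed <- stage_seed(cfg$seed, "cars") + match(tag, cfg$transforms)
      res <- run_cars(s$values[, keep, drop = FALSE],
                      sel_som$som_g_per_kg, ccfg,
                      wavelengths_nm = s$wavelengths_nm[keep])
      cars_bands[[tag]] <- res$best_bands_nm
      log_stage("CARS on %s: %d/%d bands, RMSECV %.2f g/kg", tag,
                length(res$best_band_idx), length(keep), res$best_rmsecv)
      cols <- match(res$best_bands_nm, spectra[[tag]]$wavelengths_nm)
      feats[[tag]] <- spectra[[tag]]$values[, cols, drop = FALSE]
    }
    feature_sets$CARS <- feats
  }

  rows <- list(); reports <- list()
  for (route in names(feature_sets)) {
    for (tag in names(feature_sets[[route]])) {
      X <- feature_sets[[route]][[tag]]
      for (mname in names(cfg$models)) {
        spec <- cfg$models[[mname]]
        spec$seed <- stage_seed(cfg$seed, "model") +
          length(rows)  # distinct, reproducible per combination
        label <- if (tag == "index") sprintf("%s-%s", route, mname)
                 else sprintf("%s-%s-%s", route, tag, mname)
        log_stage("fitting %s (%d features)", label, ncol(X))
        mf <- fit_predict_model(spec, X[cal, , drop = FALSE], y[cal],
                                X[val, , drop = FALSE])
        rep <- evaluate_predictions(y[val], mf$pred_val, y[cal], mf$pred_cal)
        reports[[label]] <- rep
        rows[[length(rows) + 1L]] <- data.frame(
          model = label, route = route,
          transform = if (tag == "index") NA_character_ else tag,
          method = spec$method, n_features = ncol(X),
          r2_cal = rep$r2_cal, rmse_cal = rep$rmse_cal,
          r2_val = rep$r2_val, rmse_val = rep$rmse_val,
          rpd = rep$rpd, lccc = rep$lccc, rpd_class = rep$rpd_class,
          stringsAsFactors = FALSE)
      }
    }
  }
  evaluations <- do.call(rbind, rows)
  provenance <- list(
    seed = cfg$seed,
    selection_mode = cfg$selection_mode,
    selection_on_all_samples = cfg$selection_mode == "paper",
    n_samples = n, n_calibration = length(cal),
    package_version = as.character(utils::packageVersion("somspec")),
    r_version = R.version.string,
    config_digest = config_digest(cfg))
  log_stage("done: %d model evaluations", nrow(evaluations))
  structure(list(evaluations = evaluations, index_defs = index_defs,
                 cars_bands = cars_bands, split = split, reports = reports,
                 provenance = provenance),
            class = "report_bundle")
}

# stable content digest without extra dependencies: polynomial rolling hash
# over the serialised config
config_digest <- function(cfg) {
  bytes <- as.double(serialize(cfg, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a report bundle to disk
#'
#' Emits `evaluations.csv` (one row per model run, the layout of the study's
#' accuracy tables), `index_defs.csv` (the selected optimal indexes),
#' `cars_bands.json` (selected wavelengths per transform) and
#' `provenance.json` into `dir`.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$evaluations, file.path(dir, "evaluations.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$index_defs))
    utils::write.csv(bundle$index_defs, file.path(dir, "index_defs.csv"),
                     row.names = FALSE)
  jsonlite::write_json(bundle$cars_bands, file.path(dir, "cars_bands.json"),
                       digits = NA)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
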
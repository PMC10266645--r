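#' Model specification
#'
#' Declares one of the four regression families and its hyperparameter grid.
#' Grid search minimises K-fold cross-validated RMSE on the calibration set,
#' then the winning configuration is refitted on the full calibration set.
#'
#' Default grids:
#' \itemize{
#'   \item `RF`: `mtry` 1-5, `ntree` \{100, 500, 1000, 1500, 2000\}.
#'   \item `SVR`: linear kernel, cost `2^(-4..4)` (integer exponents).
#'   \item `DNN`: hidden layers 400/600/500, ReLU, per-layer dropout
#'     0.9/0.8/0.7, 1000 epochs, L1 in \{0, 1e-5, 1e-4\}.
#'   \item `PLSR`: components 1..min(20, p, n_cal - 1), chosen by CV
#'     (minimum RMSE, ties to fewer components).
#' }
#'
#' @param method `"RF"`, `"SVR"`, `"DNN"` or `"PLSR"`.
#' @param grid optional named list overriding grid fields (e.g.
#'   `list(ntree = c(100, 500))`; for DNN also `hidden`, `dropout`,
#'   `epochs`, `lr`).
#' @param cv_folds cross-validation folds (default 10).
#' @param seed RNG seed controlling folds and stochastic fits.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(method = c("RF", "SVR", "DNN", "PLSR"), grid = NULL,
                       cv_folds = 10L, seed = 1L) {
  method <- match.arg(method)
  default <- switch(method,
    RF = list(mtry = 1:5, ntree = c(100L, 500L, 1000L, 1500L, 2000L)),
    SVR = list(cost = 2^(-4:4)),
    DNN = list(l1 = c(0, 1e-5, 1e-4), hidden = c(400L, 600L, 500L),
               dropout = c(0.9, 0.8, 0.7), epochs = 1000L, lr = 1e-3),
    PLSR = list(ncomp_max = 20L))
  if (!is.null(grid)) default[names(grid)] <- grid
  structure(list(method = method, grid = default,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "model_spec")
}

fit_one <- function(method, params, X, y, seed) {
  switch(method,
    RF = {
      set.seed(seed)
      randomForest::randomForest(
        x = X, y = y, mtry = min(params$mtry, ncol(X)), ntree = params$ntree)
    },
    SVR = e1071::svm(x = X, y = y, kernel = "linear", cost = params$cost,
                     scale = apply(X, 2L, stats::sd) > 0),
    DNN = mlp_fit(X, y, hidden = params$hidden, dropout = params$dropout,
                  l1 = params$l1, epochs = params$epochs, lr = params$lr,
                  seed = seed),
    PLSR = simpls_fit(X, y, params$ncomp))
}

predict_one <- function(method, fit, X) {
  switch(method,
    RF = as.vector(stats::predict(fit, X)),
    SVR = as.vector(stats::predict(fit, X)),
    DNN = mlp_predict(fit, X),
    PLSR = simpls_predict(fit, X))
}

expand_param_grid <- function(method, grid, p, n_cal) {
  switch(method,
    RF = {
      g <- expand.grid(mtry = pmin(grid$mtry, p), ntree = grid$ntree)
      g <- unique(g)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    SVR = lapply(grid$cost, function(cc) list(cost = cc)),
    DNN = lapply(grid$l1, function(l1)
      list(l1 = l1, hidden = grid$hidden, dropout = grid$dropout,
           epochs = grid$epochs, lr = grid$lr)),
    PLSR = NULL)  # handled by one CV pass over all component counts
}

#' Fit one model family with grid-searched cross-validation
#'
#' Hyperparameters are chosen by grid search minimising the K-fold
#' cross-validated RMSE on the calibration set (ties to the earlier grid
#' row); the winner is refitted on the full calibration set. PLSR is
#' special-cased: one CV pass scores every component count at once. All
#' randomness (fold assignment, forest/network initialisation) derives from
#' `spec$seed`, so results are fully reproducible.
#'
#' @param spec a [model_spec()].
#' @param X_cal,y_cal calibration predictors and SOM (g/kg).
#' @param X_val validation predictors (may have zero rows).
#' @return List of class `model_fit`: `method`, `best_params`, `cv_rmse`
#'   (winning CV RMSE, g/kg), `pred_cal`, `pred_val`, `fit`.
#' @export
fit_predict_model <- function(spec, X_cal, y_cal, X_val) {
  stopifnot(inherits(spec, "model_spec"))
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  n <- nrow(X_cal)
  stopifnot(length(y_cal) == n, n >= spec$cv_folds)
  if (stats::var(y_cal) <= 0)
    stop("calibration response has zero variance", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  folds <- make_folds(n, spec$cv_folds)

  if (spec$method == "PLSR") {
    ncomp_max <- min(spec$grid$ncomp_max, ncol(X_cal), n - 2L)
    set.seed(spec$seed)
    cv <- pls_cv_rmse(X_cal, y_cal, ncomp_max = ncomp_max,
                      folds = spec$cv_folds)
    best_params <- list(ncomp = cv$best_ncomp)
    best_rmse <- cv$best_rmse
  } else if (length(grid <- expand_param_grid(spec$method, spec$grid,
                                              ncol(X_cal), n)) == 1L) {
    # singleton grid: nothing to search
    best_params <- grid[[1L]]
    best_rmse <- NA_real_
  } else {
    cv_rmse <- vapply(grid, function(params) {
      sse <- 0
      for (f in folds) {
        fit <- fit_one(spec$method, params, X_cal[-f, , drop = FALSE],
                       y_cal[-f], seed = spec$seed)
        pred <- predict_one(spec$method, fit, X_cal[f, , drop = FALSE])
        sse <- sse + sum((y_cal[f] - pred)^2)
      }
      sqrt(sse / n)
    }, numeric(1L))
    best <- which.min(cv_rmse)
    best_params <- grid[[best]]
    best_rmse <- cv_rmse[best]
  }
  fit <- fit_one(spec$method, best_params, X_cal, y_cal, seed = spec$seed)
  structure(list(method = spec$method, best_params = best_params,
                 cv_rmse = best_rmse,
                 pred_cal = predict_one(spec$method, fit, X_cal),
                 pred_val = if (nrow(X_val))
                   predict_one(spec$method, fit, X_val) else numeric(0),
                 fit = fit),
            class = "model_fit")
}
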
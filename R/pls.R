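#' Univariate SIMPLS partial least squares regression
#'
#' Minimal, fast SIMPLS (de Jong 1993) for a single response, returning the
#' regression coefficients of every submodel with 1..`ncomp` latent
#' variables from one decomposition. This is the workhorse inside CARS, where
#' tens of thousands of PLS fits are needed.
#'
#' Components are truncated early if a score norm collapses (rank-deficient
#' X), so `ncomp` in the result may be smaller than requested.
#'
#' @param X numeric matrix (n x p), predictors.
#' @param y numeric vector length n, response.
#' @param ncomp maximum number of latent variables.
#' @return List with `coef` (p x A matrix; column a = coefficients of the
#'   a-component model, on the original scale), `x_means`, `y_mean`, `ncomp`.
#' @export
simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means)
  yc <- y - y_mean
  s <- crossprod(Xc, yc)                # p x 1
  R <- matrix(0, p, ncomp)
  Vb <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t <- t / nt
    r <- r / nt
    pa <- crossprod(Xc, t)              # loading
    qa <- sum(yc * t)
    v <- pa
    if (a > 1L) {
      Vp <- Vb[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; Vb[, a] <- v; Q[a] <- qa
    a_done <- a
  }
  if (a_done == 0L)
    stop("PLS fit failed: predictors have no variance", call. = FALSE)
  Bk <- R[, seq_len(a_done), drop = FALSE] *
    rep(Q[seq_len(a_done)], each = p)
  # column a of coef = rowSums of Bk[, 1:a]: one triangular matmul
  U <- upper.tri(diag(a_done), diag = TRUE) * 1
  coef <- Bk %*% U
  list(coef = coef, x_means = x_means, y_mean = y_mean, ncomp = a_done)
}

#' Predict from a SIMPLS fit
#'
#' @param fit result of [simpls_fit()].
#' @param X new predictor matrix on the columns the model was fitted with.
#' @param ncomp number of components to use (default: all fitted).
#' @return Numeric vector of predictions.
#' @export
simpls_predict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  Xc <- sweep(as.matrix(X), 2L, fit$x_means)
  as.vector(Xc %*% fit$coef[, ncomp]) + fit$y_mean
}

# Deterministic fold assignment: permute 1..n with the current RNG stream and
# deal into `folds` groups of near-equal size.
make_folds <- function(n, folds) {
  folds <- min(folds, n)
  split(sample.int(n), rep_len(seq_len(folds), n))
}

#' Cross-validated RMSE of PLS over component counts
#'
#' K-fold cross-validation of [simpls_fit()]; one decomposition per fold
#' yields predictions for every component count at once.
#'
#' @param X,y data.
#' @param ncomp_max maximum components considered.
#' @param folds number of CV folds.
#' @return List with `rmse` (vector over 1..ncomp_max; NA where a count was
#'   unreachable in some fold), `best_ncomp` (minimum RMSE, ties to fewer
#'   components) and `best_rmse`.
#' @export
pls_cv_rmse <- function(X, y, ncomp_max = 10L, folds = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  ncomp_max <- min(ncomp_max, ncol(X), n - 2L)
  ncomp_max <- max(ncomp_max, 1L)
  fold_idx <- make_folds(n, folds)
  sse <- numeric(ncomp_max)
  reached <- rep(TRUE, ncomp_max)
  for (f in fold_idx) {
    fit <- simpls_fit(X[-f, , drop = FALSE], y[-f], ncomp_max)
    Xc <- sweep(X[f, , drop = FALSE], 2L, fit$x_means)
    pred <- Xc %*% fit$coef + fit$y_mean   # n_f x ncomp fitted
    a_fit <- fit$ncomp
    if (a_fit < ncomp_max) reached[(a_fit + 1L):ncomp_max] <- FALSE
    for (a in seq_len(a_fit))
      sse[a] <- sse[a] + sum((y[f] - pred[, a])^2)
  }
  rmse <- sqrt(sse / n)
  rmse[!reached] <- NA_real_
  best <- which.min(rmse)  # first minimum = fewest components on ties
  list(rmse = rmse, best_ncomp = best, best_rmse = rmse[best])
}
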
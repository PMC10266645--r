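# Dense feed-forward regression network trained with Adam.
#
# Small MLP tailored to tabular chemometric data: ReLU hidden layers,
# inverted dropout on the hidden activations, optional L1 weight penalty,
# full-batch training for a fixed number of epochs (no early stopping), and
# z-standardisation of inputs and target. Everything is plain matrix algebra,
# so a fit is deterministic given the seed.

mlp_init <- function(sizes) {
  # He initialisation for ReLU layers
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Fit a deep feed-forward network for regression
#'
#' ReLU hidden layers with per-layer inverted dropout, L1 weight
#' regularisation, Adam optimiser, full-batch gradient descent for a fixed
#' number of epochs. Inputs and target are z-standardised internally;
#' predictions are returned on the original scale via [mlp_predict()].
#'
#' @param X predictor matrix (n x p).
#' @param y numeric response.
#' @param hidden hidden layer sizes, e.g. `c(400, 600, 500)`.
#' @param dropout fraction of units dropped per hidden layer (same length as
#'   `hidden`), e.g. `c(0.9, 0.8, 0.7)`.
#' @param l1 L1 penalty on weights (0 disables).
#' @param epochs training epochs (fixed; no early stopping).
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialisation and dropout masks.
#' @return List of class `mlp_fit` (weights, scalers, architecture).
#' @export
mlp_fit <- function(X, y, hidden = c(400L, 600L, 500L),
                    dropout = c(0.9, 0.8, 0.7), l1 = 0, epochs = 1000L,
                    lr = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(length(dropout) == length(hidden))
  n <- nrow(X)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd <= 0) stop("response has zero variance", call. = FALSE)
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  ys <- (y - y_mean) / y_sd

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  par <- mlp_init(sizes)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  for (ep in seq_len(epochs)) {
    # forward with inverted dropout on hidden activations
    A <- vector("list", L + 1L); A[[1L]] <- Xs
    masks <- vector("list", L)
    for (l in seq_len(L)) {
      Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
      if (l < L) {
        Z[Z < 0] <- 0
        if (dropout[l] > 0) {
          keep <- 1 - dropout[l]
          m <- matrix(stats::rbinom(length(Z), 1L, keep) / keep,
                      nrow(Z), ncol(Z))
          Z <- Z * m
          masks[[l]] <- m
        }
      }
      A[[l + 1L]] <- Z
    }
    delta <- 2 * (A[[L + 1L]] - ys) / n       # d(MSE)/d(output)
    for (l in L:1) {
      gW <- crossprod(A[[l]], delta)
      if (l1 > 0) gW <- gW + l1 * sign(par$W[[l]])
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- delta %*% t(par$W[[l]])
        delta[A[[l]] <= 0] <- 0               # ReLU gate (post-dropout acts)
        if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
      }
      # Adam update
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      mh <- mW[[l]] / (1 - b1^ep); vh <- vW[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mh / (sqrt(vh) + eps)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  structure(list(W = par$W, b = par$b, hidden = hidden,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd),
            class = "mlp_fit")
}

#' Predict from a fitted network
#'
#' @param fit an `mlp_fit`.
#' @param X new predictor matrix.
#' @return Numeric vector of predictions on the original response scale.
#' @export
mlp_predict <- function(fit, X) {
  A <- sweep(sweep(as.matrix(X), 2L, fit$x_mean), 2L, fit$x_sd, "/")
  L <- length(fit$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    if (l < L) A[A < 0] <- 0
  }
  as.vector(A) * fit$y_sd + fit$y_mean
}
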
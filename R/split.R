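#' Kennard-Stone calibration/validation split
#'
#' Classical deterministic max-min selection in Euclidean feature space: seed
#' with the two most distant samples, then repeatedly add the sample whose
#' minimum distance to the already-selected set is largest, until `n_cal`
#' samples are selected. The remainder forms the validation set. Ties are
#' broken toward the lower row index.
#'
#' @param X numeric matrix (samples x features) with no missing values;
#'   typically the smoothed reflectance spectra.
#' @param n_cal number of calibration samples (2..n).
#' @param sample_ids optional ids (defaults to rownames or 1..n as character).
#' @return List of class `ks_split` with `calibration_ids`, `validation_ids`,
#'   `calibration_idx`, `validation_idx`.
#' @export
kennard_stone_split <- function(X, n_cal, sample_ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (n_cal < 2L) stop("n_cal must be at least 2", call. = FALSE)
  if (n_cal > n) stop("n_cal exceeds sample count", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  }
  D <- as.matrix(stats::dist(X))
  # seed pair: globally maximal distance; ties to lowest (row, col) indices
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[far[, 1L] < far[, 2L], , drop = FALSE]
  far <- far[order(far[, 1L], far[, 2L]), , drop = FALSE]
  sel <- c(far[1L, 1L], far[1L, 2L])
  if (n_cal > 2L) {
    min_d <- pmin(D[, sel[1L]], D[, sel[2L]])
    min_d[sel] <- -Inf
    for (step in 3:n_cal) {
      nxt <- which.max(min_d)           # first maximum = lowest index on ties
      sel <- c(sel, nxt)
      min_d <- pmin(min_d, D[, nxt])
      min_d[nxt] <- -Inf
    }
  }
  sel <- as.integer(sel)
  val <- setdiff(seq_len(n), sel)
  structure(list(calibration_ids = sample_ids[sel],
                 validation_ids = sample_ids[val],
                 calibration_idx = sel, validation_idx = val),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d validation samples\n",
              length(x$calibration_idx), length(x$validation_idx)))
  invisible(x)
}
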
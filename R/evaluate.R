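#' RPD quality class
#'
#' Chang's three-level interpretation of the ratio of performance to
#' deviation: below 1.4 the model has poor estimation capability; between 1.4
#' and 2.0 (inclusive) moderate; above 2.0 considerably high precision.
#'
#' @param rpd positive ratio (may be `Inf` for a perfect fit).
#' @return `"poor"`, `"moderate"` or `"high"`.
#' @export
rpd_class <- function(rpd) {
  if (!is.numeric(rpd) || length(rpd) != 1L || is.na(rpd) || rpd <= 0)
    stop("rpd must be a positive number", call. = FALSE)
  if (rpd < 1.4) "poor" else if (rpd <= 2.0) "moderate" else "high"
}

#' Regression evaluation suite: R2, RMSE, RPD, LCCC
#'
#' Computes the standard chemometric accuracy metrics on the validation
#' (prediction) set and optionally on the calibration set:
#' \itemize{
#'   \item `R2 = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`
#'   \item `RMSE = sqrt(mean((O - P)^2))` (divisor n)
#'   \item `RPD = s_o / RMSE`, with `s_o` the sample standard deviation of
#'     the observations (divisor n - 1)
#'   \item `LCCC = 2 r s_o s_p / (s_o^2 + s_p^2 + (mean(O) - mean(P))^2)`,
#'     Lin's concordance correlation coefficient with sample standard
#'     deviations
#' }
#' A degenerate constant prediction has `s_p = 0`, hence `LCCC = 0`. A
#' perfect prediction has `RMSE = 0` and `RPD = Inf` (class `"high"`).
#'
#' @param obs,pred observed and predicted values of the validation set.
#' @param obs_cal,pred_cal optional calibration-set values.
#' @return List of class `eval_report`: `r2_cal`, `rmse_cal` (NA when no
#'   calibration data given), `r2_val`, `rmse_val`, `rpd`, `lccc`,
#'   `rpd_class`, `n_val`.
#' @export
evaluate_predictions <- function(obs, pred, obs_cal = NULL, pred_cal = NULL) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  if (stats::var(obs) <= 0)
    stop("observations have zero variance", call. = FALSE)
  n <- length(obs)
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / n)
  s_o <- stats::sd(obs)
  rpd <- if (rmse == 0) Inf else s_o / rmse
  s_p <- stats::sd(pred)
  lccc <- if (s_p == 0) 0 else {
    r <- stats::cor(obs, pred)
    2 * r * s_o * s_p / (s_o^2 + s_p^2 + (mean(obs) - mean(pred))^2)
  }
  r2_cal <- rmse_cal <- NA_real_
  if (!is.null(obs_cal)) {
    stopifnot(length(obs_cal) == length(pred_cal))
    sse_c <- sum((obs_cal - pred_cal)^2)
    r2_cal <- 1 - sse_c / sum((obs_cal - mean(obs_cal))^2)
    rmse_cal <- sqrt(sse_c / length(obs_cal))
  }
  structure(list(r2_cal = r2_cal, rmse_cal = rmse_cal,
                 r2_val = r2, rmse_val = rmse,
                 rpd = rpd, lccc = lccc, rpd_class = rpd_class(rpd),
                 n_val = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> cal: R2 = %.3f RMSE = %.3f | ",
                     "val: R2 = %.3f RMSE = %.3f g/kg | RPD = %.2f (%s), ",
                     "LCCC = %.3f\n"),
              x$r2_cal, x$rmse_cal, x$r2_val, x$rmse_val, x$rpd,
              x$rpd_class, x$lccc))
  invisible(x)
}
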
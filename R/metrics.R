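#' Node-level regression metrics
#'
#' Computes the five evaluation metrics used throughout the package:
#' MAPE (with an `eps` floor on the denominator), MSE, RMSE, MAE, and
#' R-squared (`1 - SS_res / SS_tot`). Masked cells must be removed by the
#' caller before calling.
#'
#' @param y_true observed values (length >= 2; R-squared is undefined
#'   below that).
#' @param y_pred predicted values, same length.
#' @param eps MAPE denominator floor.
#' @return A list of class `metric_report` with elements `mape`, `mse`,
#'   `rmse`, `mae`, `r2`, `n_eval`.
#' @export
regression_metrics <- function(y_true, y_pred, eps = 1e-3) {
  assert_that(length(y_true) == length(y_pred), "length mismatch")
  if (length(y_true) < 2) stop("need at least 2 values (R2 undefined)")
  err <- y_true - y_pred
  mse <- mean(err^2)
  out <- list(mape = mape(y_true, y_pred, eps),
              mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
              r2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2),
              n_eval = length(y_true))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("  MAPE %.4f | MSE %.5f | RMSE %.4f | MAE %.4f | R2 %.4f  (n = %d)\n",
              x$mape, x$mse, x$rmse, x$mae, x$r2, x$n_eval))
  invisible(x)
}
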
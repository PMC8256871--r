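#' Prediction-accuracy metrics
#'
#' Computes the validation metrics used to compare biomass prediction models:
#' mean absolute error `MAE = mean(|actual - predicted|)`, mean squared error,
#' `RMSE = sqrt(MSE)`, the coefficient of determination
#' `R2 = 1 - SSres/SStot`, and `R2_cor`, the squared Pearson correlation
#' between observed and predicted values (the form reported for resamples,
#' bounded in [0, 1]). For any input `RMSE >= MAE`, with equality exactly
#' when all residuals have the same magnitude.
#'
#' @param actual,predicted numeric vectors of equal length >= 2, finite.
#' @return list with `MAE`, `MSE`, `RMSE`, `R2`, `R2_cor`. When `actual` has
#'   zero variance, both R-squared forms are `NA` (undefined signal).
#' @examples
#' compute_metrics(c(2, 4, 6, 8), c(3, 3, 7, 7))  # MAE 1, RMSE 1, R2 0.8
#' @export
compute_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2) {
    pg_stop("input", "compute_metrics: need equal-length vectors of length >= 2")
  }
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    pg_stop("input", "compute_metrics: non-finite values")
  }
  res <- actual - predicted
  mae <- mean(abs(res))
  mse <- mean(res^2)
  sstot <- sum((actual - mean(actual))^2)
  if (sstot == 0) {
    r2 <- NA_real_; r2c <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / sstot
    r2c <- if (sd(predicted) == 0) NA_real_ else cor(actual, predicted)^2
  }
  list(MAE = mae, MSE = mse, RMSE = sqrt(mse), R2 = r2, R2_cor = r2c)
}
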
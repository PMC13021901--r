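#' The four-statistic evaluation report
#'
#' Computes the model-comparison statistics used throughout the package:
#' \itemize{
#'   \item `r2`: sum-of-squares definition, `1 - SSE/SST` (can be negative);
#'   \item `rmse`: root mean square error, in target units;
#'   \item `aard_percent`: average absolute relative deviation,
#'     `(100/n) * sum(|y_i - yhat_i| / y_i)`, the field-standard
#'     solubility-correlation error measure;
#'   \item `max_error`: largest absolute residual.
#' }
#'
#' @param y_true Observed targets; strictly positive (AARD divides by them).
#' @param y_pred Predictions, same length.
#' @return A one-row tibble with columns `r2`, `rmse`, `aard_percent`,
#'   `max_error`, `n`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length",
      class = "solubag_validation_error"
    )
  }
  if (length(y_true) < 2) {
    abort("at least 2 observations are required", class = "solubag_validation_error")
  }
  if (any(y_true <= 0)) {
    abort("y_true must be strictly positive", class = "solubag_domain_error")
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) {
    abort("r2 undefined: y_true has zero variance",
      class = "solubag_zero_variance_error"
    )
  }
  res <- y_true - y_pred
  tibble::tibble(
    r2 = 1 - sum(res^2) / sst,
    rmse = sqrt(mean(res^2)),
    aard_percent = 100 * mean(abs(res) / y_true),
    max_error = max(abs(res)),
    n = length(y_true)
  )
}

#' Aggregate per-fold metric reports
#'
#' Mean and sample standard deviation (n-1 denominator) of each metric over
#' cross-validation folds, as reported in mean +/- SD tables.
#'
#' @param per_fold A data frame of per-fold [regression_metrics()] rows
#'   (at least 2 rows).
#' @return A tibble with columns `metric`, `mean`, `sd`.
#' @export
aggregate_cv <- function(per_fold) {
  if (nrow(per_fold) < 2) {
    abort("at least 2 folds are required", class = "solubag_validation_error")
  }
  per_fold |>
    dplyr::select(dplyr::all_of(c("r2", "rmse", "aard_percent", "max_error"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$metric, c("r2", "rmse", "aard_percent", "max_error")))
}
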
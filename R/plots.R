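#' Plot study metrics
#'
#' Bar chart of one evaluation metric per model and output.
#'
#' @param object A `"solubag_study"`.
#' @param metric Which metric column to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.solubag_study <- function(object, metric = c("r2", "rmse", "aard_percent", "max_error"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(
    object$metrics,
    ggplot2::aes(x = .data$family, y = .data[[metric]], fill = .data$family)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target), scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric)
}

#' Plot an effect curve
#'
#' @param curve A tibble from [effect_curve()].
#' @return A ggplot object.
#' @export
plot_effect_curve <- function(curve) {
  varying <- if (length(unique(curve$T_K)) > 1) "T_K" else "P_bar"
  ggplot2::ggplot(curve, ggplot2::aes(x = .data[[varying]], y = .data$.pred)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = curve[curve$extrapolated, ], colour = "red") +
    ggplot2::labs(x = varying, y = "prediction")
}

#' Plot a response surface
#'
#' @param surface A tibble from [effect_surface()].
#' @return A ggplot object.
#' @export
plot_effect_surface <- function(surface) {
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$P_bar, y = .data$T_K, fill = .data$.pred)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "prediction")
}

#' Plot permutation importance shares
#'
#' @param importance A tibble from [feature_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(
    importance,
    ggplot2::aes(x = .data$feature, y = .data$share, fill = .data$feature)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "importance share")
}
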
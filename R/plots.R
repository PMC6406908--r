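#' Plot fold-change trajectories for selected fields
#'
#' Line plot of the year-over-year fold change of each field's annual impact
#' index, with the no-change level (fold 1) marked.
#'
#' @param delta Fold-change table from [delta_aii()].
#' @param fields Optional character vector of fields to show (default all).
#' @return A ggplot object.
#' @export
plot_delta_trends <- function(delta, fields = NULL) {
  if (!is.null(fields)) {
    missing_f <- setdiff(fields, unique(delta$field))
    if (length(missing_f) > 0L) {
      stop_lookup(sprintf("Unknown field(s): %s", paste(missing_f, collapse = ", ")))
    }
    delta <- delta[delta$field %in% fields, , drop = FALSE]
  }
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$year, y = .data$delta_aii,
                                      colour = .data$field)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(delta$year)) +
    ggplot2::labs(x = "Year", y = "Fold change of annual impact index",
                  colour = "Field") +
    ggplot2::theme_minimal()
}

#' @describeIn forecast_fields Bar chart of the predicted top-k fields,
#'   ordered by predicted fold change.
#' @param object A `field_forecast` object.
#' @export
autoplot.field_forecast <- function(object, ...) {
  top <- utils::head(object$predictions, object$top_k)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$field, .data$predicted_delta_aii),
    y = .data$predicted_delta_aii)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Predicted fold change",
      title = sprintf("Predicted top-%d fields, %d (degree-%d trend)",
                      object$top_k, object$target_year, object$degree)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_backtest Pooled top-k accuracy per horizon against the
#'   coincidence baseline.
#' @param object A `trend_backtest` object.
#' @export
autoplot.trend_backtest <- function(object, ...) {
  ggplot2::ggplot(object$horizons,
                  ggplot2::aes(x = factor(.data$horizon), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$p0, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::annotate("text", x = Inf, y = object$p0, hjust = 1.1, vjust = -0.5,
                      colour = "firebrick",
                      label = sprintf("coincidence %.1f%%", 100 * object$p0)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Forecast horizon (years)", y = "Pooled top-k accuracy",
                  title = sprintf("Backtest, degree-%d trend", object$degree)) +
    ggplot2::theme_minimal()
}
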
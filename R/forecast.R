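#' Fit a least-squares polynomial trend
#'
#' Fits a degree-`degree` polynomial to `(t, y)` points by ordinary least
#' squares, minimizing the residual sum of squares. The solve uses the QR
#' factorization of the Vandermonde basis (numerically stable); with exactly
#' `degree + 1` points the fit interpolates.
#'
#' @param t Strictly increasing time indices.
#' @param y Observed values (here, fold changes of the annual impact index).
#' @param degree Polynomial degree, 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return Numeric coefficient vector of length `degree + 1`, ascending
#'   powers, named `b0`, `b1`, ...
#' @examples
#' fit_polynomial_trend(1:5, c(1, 2, 3, 4, 5), degree = 1)  # b0 = 0, b1 = 1
#' @export
fit_polynomial_trend <- function(t, y, degree) {
  if (!is_whole(degree) || degree < 1 || degree > 3) {
    stop_domain("`degree` must be 1, 2 or 3.")
  }
  if (length(t) != length(y)) stop_fit("`t` and `y` must have equal length.")
  if (anyDuplicated(t)) stop_fit("Time indices must be distinct.")
  if (is.unsorted(t, strictly = TRUE)) stop_fit("Time indices must be strictly increasing.")
  if (length(t) < degree + 1L) {
    stop_fit(sprintf("Need at least %d points for a degree-%d fit; got %d.",
                     degree + 1L, degree, length(t)))
  }
  X <- outer(as.numeric(t), 0:degree, `^`)
  fit <- stats::lm.fit(X, as.numeric(y))
  setNames(fit$coefficients, paste0("b", 0:degree))
}

#' Evaluate a polynomial at given points
#'
#' @param coefficients Ascending-power coefficient vector, as returned by
#'   [fit_polynomial_trend()].
#' @param t Evaluation points (vectorized).
#' @return Polynomial values at `t` (Horner evaluation).
#' @export
predict_polynomial <- function(coefficients, t) {
  out <- rep(0, length(t))
  for (b in rev(as.numeric(coefficients))) out <- out * t + b
  out
}

#' Extrapolate a fitted window trend
#'
#' Given a polynomial fitted on time indices `1..window_length`, returns its
#' value `horizon` years past the window end, i.e. at index
#' `window_length + horizon`.
#'
#' @inheritParams predict_polynomial
#' @param window_length Number of points the trend was fitted on.
#' @param horizon Years ahead of the window end (\eqn{\ge 1}).
#' @return A single double.
#' @export
extrapolate <- function(coefficients, window_length, horizon) {
  if (!is_whole(horizon) || horizon < 1) stop_domain("`horizon` must be an integer >= 1.")
  predict_polynomial(coefficients, window_length + horizon)
}

#' Forecast fold-change trends for all fields and rank a predicted top-k
#'
#' For every field, fits a polynomial to the `window_length` fold-change
#' values ending at `end_year` (on internal time indices `1..window_length`;
#' calendar years map affinely, which leaves polynomial predictions
#' unchanged), extrapolates `horizon` years past the window, and ranks fields
#' by predicted fold change descending. Ties are broken lexicographically by
#' field name so the ranking is deterministic. Extrapolated values \eqn{\le 0}
#' are ranked as-is but flagged, since a true fold change is positive.
#'
#' @param delta Fold-change table from [delta_aii()] (`field`, `year`,
#'   `delta_aii`).
#' @param end_year Last year of the fitting window.
#' @param degree Polynomial degree (1-3); linear is the recommended default.
#' @param window_length Window length in years (default 5).
#' @param horizon Years past the window the prediction targets (1-3).
#' @param top_k Size of the predicted head of the ranking (default 20).
#' @return A `field_forecast` object: a list with `predictions` (tibble
#'   `field`, `predicted_delta_aii`, `rank`, `in_top_k`, `nonpositive`),
#'   `top_k_fields` (character, rank order) and the settings used
#'   (`target_year = end_year + horizon`, `degree`, `window_length`,
#'   `horizon`, `top_k`, `end_year`). Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
forecast_fields <- function(delta, end_year, degree = 1, window_length = 5,
                            horizon = 1, top_k = 20) {
  if (!is_whole(window_length) || window_length < degree + 1) {
    stop_config("`window_length` must be an integer >= degree + 1.")
  }
  if (!is_whole(horizon) || horizon < 1) stop_config("`horizon` must be an integer >= 1.")
  if (!is_whole(top_k) || top_k < 1) stop_config("`top_k` must be an integer >= 1.")

  window_years <- seq(end_year - window_length + 1, end_year)
  win <- delta |>
    dplyr::filter(.data$year %in% window_years) |>
    dplyr::arrange(.data$field, .data$year)
  n_per_field <- win |> dplyr::count(.data$field)
  incomplete <- union(
    n_per_field$field[n_per_field$n < window_length],
    setdiff(unique(delta$field), n_per_field$field))
  if (length(incomplete) > 0L) {
    stop_validation(sprintf(
      "Field(s) missing fold-change values in the window %d-%d: %s",
      min(window_years), max(window_years), paste(sort(incomplete), collapse = ", ")))
  }

  predictions <- win |>
    dplyr::group_by(.data$field) |>
    dplyr::summarise(
      predicted_delta_aii = extrapolate(
        fit_polynomial_trend(seq_len(window_length), .data$delta_aii, degree),
        window_length, horizon),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$predicted_delta_aii), .data$field) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  in_top_k = .data$rank <= top_k,
                  nonpositive = .data$predicted_delta_aii <= 0)

  structure(
    list(predictions = predictions,
         top_k_fields = predictions$field[predictions$in_top_k],
         target_year = as.integer(end_year + horizon),
         end_year = as.integer(end_year),
         degree = as.integer(degree),
         window_length = as.integer(window_length),
         horizon = as.integer(horizon),
         top_k = as.integer(top_k)),
    class = "field_forecast")
}

#' @export
print.field_forecast <- function(x, ...) {
  cat(sprintf(
    "<field_forecast> degree-%d polynomial, window %d-%d, target year %d\n",
    x$degree, x$end_year - x$window_length + 1L, x$end_year, x$target_year))
  cat(sprintf("Top %d of %d fields by predicted fold change:\n",
              x$top_k, nrow(x$predictions)))
  print(utils::head(x$predictions, x$top_k), ...)
  invisible(x)
}

#' @describeIn forecast_fields Per-field predictions as a tibble.
#' @param x A `field_forecast` object.
#' @param ... Unused.
#' @export
tidy.field_forecast <- function(x, ...) x$predictions

#' @describeIn forecast_fields One-row summary of the forecast settings.
#' @export
glance.field_forecast <- function(x, ...) {
  tibble::tibble(degree = x$degree, window_length = x$window_length,
                 horizon = x$horizon, top_k = x$top_k,
                 end_year = x$end_year, target_year = x$target_year,
                 n_fields = nrow(x$predictions),
                 n_nonpositive = sum(x$predictions$nonpositive))
}
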
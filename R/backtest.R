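#' Fraction of fields predicted within a tolerance
#'
#' Point accuracy of fold-change predictions: the share of fields whose
#' predicted value lies within `tolerance` of the actual value in absolute
#' fold units, \eqn{|pred - actual| \le tol}. The default tolerance of 1.0
#' fold matches the headline "within an error of 1.0-fold" reading; the
#' multiplicative alternative is deliberately not used because the compared
#' quantity is itself already a fold change.
#'
#' @param predicted,actual Named numeric vectors over the same field set.
#' @param tolerance Positive absolute tolerance in fold units (default 1.0).
#' @return A fraction in `[0, 1]`.
#' @export
point_accuracy <- function(predicted, actual, tolerance = 1.0) {
  check_scalar_number(tolerance, "tolerance")
  if (tolerance <= 0) stop_config("`tolerance` must be > 0.")
  if (is.null(names(predicted)) || is.null(names(actual))) {
    stop_validation("`predicted` and `actual` must be named by field.")
  }
  if (!setequal(names(predicted), names(actual))) {
    diff <- c(setdiff(names(predicted), names(actual)),
              setdiff(names(actual), names(predicted)))
    stop_validation(sprintf("Field sets differ: %s", paste(diff, collapse = ", ")))
  }
  actual <- actual[names(predicted)]
  mean(abs(predicted - actual) <= tolerance)
}

#' Overlap between predicted and actual top-k field sets
#'
#' Rank-agnostic set intersection: a predicted field "matches" if it appears
#' anywhere in the actual top-k, regardless of position.
#'
#' @param predicted_topk,actual_topk Character vectors of length k with no
#'   duplicates.
#' @return A list with `matches` (integer intersection size) and `fraction`
#'   (`matches / k`).
#' @export
topk_overlap <- function(predicted_topk, actual_topk) {
  if (anyDuplicated(predicted_topk) || anyDuplicated(actual_topk)) {
    stop_validation("Top-k lists must not contain duplicates.")
  }
  if (length(predicted_topk) != length(actual_topk)) {
    stop_validation("Top-k lists must have equal length.")
  }
  m <- length(intersect(predicted_topk, actual_topk))
  list(matches = m, fraction = m / length(predicted_topk))
}

#' One-sided exact binomial test against a coincidence baseline
#'
#' Exact upper tail \eqn{P(X \ge matches)} for \eqn{X \sim Bin(trials, p0)}:
#' the probability of doing at least this well by picking top-k fields at
#' random. `p0` is the coincidence match rate `top_k / n_fields` (20/79 =
#' 0.253 in the default study design).
#'
#' @param matches Observed match count, `0 <= matches <= trials`.
#' @param trials Number of top-k slots tested.
#' @param p0 Null match probability in (0, 1).
#' @return The one-sided p-value in (0, 1].
#' @examples
#' binomial_match_test(23, 60, 20 / 79)  # ~0.018
#' @export
binomial_match_test <- function(matches, trials, p0) {
  if (!is_whole(matches) || !is_whole(trials) || matches < 0 || matches > trials) {
    stop_domain("Need integer 0 <= matches <= trials.")
  }
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop_domain("`p0` must lie strictly between 0 and 1.")
  }
  pbinom(matches - 1, trials, p0, lower.tail = FALSE)
}

#' Actual top-k fields at one year
#'
#' The k fields with the largest observed fold change in `year`, ranked
#' descending with lexicographic tie-breaking (the same rule the forecaster
#' uses).
#'
#' @param delta Fold-change table from [delta_aii()].
#' @param year Year to rank.
#' @param top_k Head size.
#' @return Character vector of length `top_k`, rank order.
#' @export
actual_topk <- function(delta, year, top_k) {
  slice <- delta[delta$year == year, , drop = FALSE]
  if (nrow(slice) == 0L) stop_lookup(sprintf("No fold-change values for year %s.", year))
  slice <- slice[order(-slice$delta_aii, slice$field), , drop = FALSE]
  utils::head(slice$field, top_k)
}

#' Sliding-window backtest of trend forecasts
#'
#' Validates the forecaster on held-out history. Every window of
#' `window_length` consecutive fold-change years whose target year
#' (window end + horizon) still has observed data is enumerated; for each, the
#' predicted top-k is compared with the actual top-k (rank-agnostic overlap)
#' and matches are pooled across windows per horizon, giving
#' `trials = top_k * n_windows` slots. Each pooled match rate gets a one-sided
#' exact binomial p-value against the coincidence baseline
#' `p0 = top_k / n_fields`. Point accuracy ("accuracy A") is the pooled
#' fraction of horizon-1 predictions within `tolerance` of the actual fold
#' change, over all fields and windows.
#'
#' @inheritParams forecast_fields
#' @param horizons Integer horizons to evaluate (default `1:3`).
#' @param tolerance Absolute fold-unit tolerance for point accuracy.
#' @return A `trend_backtest` object: list with `horizons` (tibble `horizon`,
#'   `windows`, `matches`, `trials`, `accuracy`, `p_value`), `accuracy_a`,
#'   `accuracy_a_matches`, `accuracy_a_trials`, `p0`, `windows` (per-window
#'   detail tibble incl. per-window p-values) and the settings used. Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_backtest <- function(delta, degree = 1, window_length = 5, horizons = 1:3,
                         top_k = 20, tolerance = 1.0) {
  years <- sort(unique(delta$year))
  fields <- sort(unique(delta$field))
  n_fields <- length(fields)
  if (top_k > n_fields) stop_config("`top_k` cannot exceed the number of fields.")
  p0 <- top_k / n_fields

  min_span <- window_length + min(horizons)
  if (length(years) < min_span) {
    stop_validation(sprintf(
      "Backtest needs at least %d fold-change years (window %d + horizon %d); got %d.",
      min_span, window_length, min(horizons), length(years)))
  }

  window_detail <- purrr::map_dfr(sort(horizons), function(h) {
    ends <- years[(years >= years[1] + window_length - 1) & (years + h <= years[length(years)])]
    purrr::map_dfr(ends, function(e) {
      fc <- forecast_fields(delta, end_year = e, degree = degree,
                            window_length = window_length, horizon = h,
                            top_k = top_k)
      ov <- topk_overlap(fc$top_k_fields, actual_topk(delta, e + h, top_k))
      tibble::tibble(horizon = h,
                     window_start = e - window_length + 1L,
                     window_end = as.integer(e),
                     target_year = as.integer(e + h),
                     matches = ov$matches, trials = as.integer(top_k),
                     accuracy = ov$fraction,
                     p_value = binomial_match_test(ov$matches, top_k, p0))
    })
  })

  pooled <- window_detail |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(windows = dplyr::n(),
                     matches = sum(.data$matches),
                     trials = sum(.data$trials), .groups = "drop") |>
    dplyr::mutate(accuracy = .data$matches / .data$trials,
                  p_value = purrr::map2_dbl(.data$matches, .data$trials,
                                            binomial_match_test, p0 = p0))

  # pooled point accuracy on horizon-1 windows
  h1_ends <- years[(years >= years[1] + window_length - 1) & (years + 1 <= years[length(years)])]
  pt <- purrr::map_dfr(h1_ends, function(e) {
    fc <- forecast_fields(delta, end_year = e, degree = degree,
                          window_length = window_length, horizon = 1L,
                          top_k = top_k)
    act <- delta[delta$year == e + 1, c("field", "delta_aii")]
    tibble::tibble(
      hit = abs(fc$predictions$predicted_delta_aii -
                  act$delta_aii[match(fc$predictions$field, act$field)]) <= tolerance)
  })

  structure(
    list(horizons = pooled,
         accuracy_a = mean(pt$hit),
         accuracy_a_matches = sum(pt$hit),
         accuracy_a_trials = nrow(pt),
         p0 = p0,
         windows = window_detail,
         degree = as.integer(degree),
         window_length = as.integer(window_length),
         top_k = as.integer(top_k),
         n_fields = n_fields,
         tolerance = tolerance),
    class = "trend_backtest")
}

#' @export
print.trend_backtest <- function(x, ...) {
  cat(sprintf(
    "<trend_backtest> degree-%d polynomial, window %d, top-%d of %d fields (p0 = %.1f%%)\n",
    x$degree, x$window_length, x$top_k, x$n_fields, 100 * x$p0))
  cat(sprintf("Point accuracy (horizon 1, +/- %.1f fold): %.1f%% (%d/%d)\n",
              x$tolerance, 100 * x$accuracy_a, x$accuracy_a_matches, x$accuracy_a_trials))
  print(x$horizons, ...)
  invisible(x)
}

#' @describeIn run_backtest Pooled per-horizon results as a tibble.
#' @param x A `trend_backtest` object.
#' @param ... Unused.
#' @export
tidy.trend_backtest <- function(x, ...) x$horizons

#' @describeIn run_backtest One-row summary: settings, baseline, point
#'   accuracy and best horizon-level p-value.
#' @export
glance.trend_backtest <- function(x, ...) {
  tibble::tibble(degree = x$degree, window_length = x$window_length,
                 top_k = x$top_k, n_fields = x$n_fields, p0 = x$p0,
                 tolerance = x$tolerance, accuracy_a = x$accuracy_a,
                 n_windows = sum(x$horizons$windows),
                 min_p_value = min(x$horizons$p_value))
}
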
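#' Annual impact of a field in one journal-year
#'
#' The annual impact (AI) is the number of articles a field placed in a
#' journal in one year, weighted by that journal's impact factor:
#' \eqn{AI = N \times IF}. It is the elementary term summed into the annual
#' impact index.
#'
#' @param count Non-negative integer article count (vectorized).
#' @param impact_factor Positive journal impact factor (vectorized).
#' @return `count * impact_factor`, a non-negative double.
#' @examples
#' annual_impact(6, 40.137)  # 240.822
#' @export
annual_impact <- function(count, impact_factor) {
  if (any(!is_whole(count) | count < 0)) {
    stop_domain("`count` must be a non-negative integer.")
  }
  if (any(!is.finite(impact_factor) | impact_factor <= 0)) {
    stop_domain("`impact_factor` must be positive and finite.")
  }
  as.numeric(count) * impact_factor
}

#' Annual impact index table
#'
#' For every (field, year) in the panel, sums the impact-factor-weighted
#' article counts over all tracked journals:
#' \deqn{AII(f, y) = \sum_j N_{f,j,y} \times IF_j.}
#' This is the field's impact-weighted publication mass for the year; a field
#' with no articles anywhere scores 0.
#'
#' @param panel Complete count-panel tibble (`field`, `journal`, `year`,
#'   `count`), e.g. from [read_count_panel()] or [simulate_panel()].
#' @param journals Journal table with `journal` and `impact_factor`; must
#'   cover every journal in the panel.
#' @return A tibble with columns `field`, `year`, `aii`, complete over the
#'   panel's fields and years.
#' @export
compute_aii <- function(panel, journals) {
  check_journals(journals)
  unknown <- setdiff(unique(panel$journal), journals$journal)
  if (length(unknown) > 0L) {
    stop_lookup(sprintf("Panel references journal(s) missing from the journal table: %s",
                        paste(unknown, collapse = ", ")))
  }
  panel |>
    dplyr::inner_join(journals[c("journal", "impact_factor")], by = "journal") |>
    dplyr::group_by(.data$field, .data$year) |>
    dplyr::summarise(aii = sum(.data$count * .data$impact_factor), .groups = "drop") |>
    dplyr::arrange(.data$field, .data$year)
}

#' Annual impact index of a single field-year
#'
#' Convenience scalar lookup over [compute_aii()].
#'
#' @inheritParams compute_aii
#' @param field Field keyword present in the panel.
#' @param year Year present in the panel.
#' @return A single non-negative double.
#' @export
annual_impact_index <- function(panel, journals, field, year) {
  if (!field %in% panel$field) stop_lookup(sprintf("Unknown field '%s'.", field))
  if (!year %in% panel$year) stop_lookup(sprintf("Year %s not in panel.", year))
  sub <- panel[panel$field == field & panel$year == year, , drop = FALSE]
  aii <- compute_aii(sub, journals)
  aii$aii[[1L]]
}

#' Year-over-year fold changes of the annual impact index
#'
#' For each field and each year after the first,
#' \eqn{\Delta AII(y) = AII(y) / AII(y-1)}, the field's momentum independent
#' of its absolute size. A zero AII makes the ratio undefined or degenerate,
#' so any zero value (numerator or denominator) is first replaced by
#' `sub_constant` — by default 1.081, the score of a single article in the
#' lowest-impact-factor tracked journal (see [derive_sub_constant()]). The
#' position substituted is recorded per row so a denominator-only reading
#' remains auditable; a year-pair with both values zero reads as "no change"
#' (fold 1).
#'
#' @param aii AII table from [compute_aii()] (`field`, `year`, `aii`).
#' @param sub_constant Positive pseudo-count replacing zero AII values.
#' @return A tibble with columns `field`, `year` (all AII years but each
#'   field's first), `delta_aii` (positive double) and `substituted`
#'   (`"none"`, `"numerator"`, `"denominator"` or `"both"`). The constant used
#'   is attached as attribute `sub_constant`.
#' @examples
#' aii <- tibble::tibble(field = "epigenetics", year = 2012:2013,
#'                       aii = c(15.760, 88.141))
#' delta_aii(aii)  # 88.141 / 15.760 = 5.593
#' @export
delta_aii <- function(aii, sub_constant = 1.081) {
  check_scalar_number(sub_constant, "sub_constant")
  if (sub_constant <= 0) stop_config("`sub_constant` must be > 0.")
  if (length(unique(aii$year)) < 2L) {
    stop_validation("Fold changes need at least two years of AII values.")
  }
  if (any(aii$aii < 0)) stop_validation("AII values must be non-negative.")
  aii |>
    dplyr::arrange(.data$field, .data$year) |>
    dplyr::group_by(.data$field) |>
    dplyr::mutate(
      prev = dplyr::lag(.data$aii),
      num = ifelse(.data$aii == 0, sub_constant, .data$aii),
      den = ifelse(.data$prev == 0, sub_constant, .data$prev),
      delta_aii = .data$num / .data$den,
      substituted = dplyr::case_when(
        .data$aii == 0 & .data$prev == 0 ~ "both",
        .data$aii == 0 ~ "numerator",
        .data$prev == 0 ~ "denominator",
        TRUE ~ "none")) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev)) |>
    dplyr::select("field", "year", "delta_aii", "substituted") |>
    structure(sub_constant = sub_constant)
}

#' Derive the zero-substitution constant from a journal table
#'
#' The pseudo-count replacing a zero AII is pinned to the smallest score a
#' field can earn: one article in the lowest-impact-factor tracked journal,
#' i.e. `min(impact_factor) * 1`.
#'
#' @param journals Journal table (`journal`, `impact_factor`).
#' @return A single positive double.
#' @export
derive_sub_constant <- function(journals) {
  check_journals(journals)
  if (nrow(journals) == 0L) stop_validation("Journal table is empty.")
  annual_impact(1L, min(journals$impact_factor))
}
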
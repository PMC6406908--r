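# Shared fixtures and independent oracles. Oracles deliberately use naive
# formulations (nested loops, normal equations, explicit tail sums) so they
# stay independent of the implementation paths they check.

example_journals <- function() {
  tibble::tibble(
    journal = c("JAMA", "Nature", "Science", "Child's nervous system"),
    impact_factor = c(44.405, 40.137, 37.205, 1.081))
}

# a small deterministic panel: counts = (field index + journal index + year
# offset) mod 4, so zeros occur but the panel is reproducible without RNG
toy_panel <- function(n_fields = 3, n_journals = 3, years = 2011:2014) {
  journals <- sprintf("J%d", seq_len(n_journals))
  fields <- sprintf("f%d", seq_len(n_fields))
  tidyr::expand_grid(field = fields, journal = journals, year = as.integer(years)) |>
    dplyr::mutate(count = as.integer(
      (match(field, fields) + match(journal, journals) + (year - years[1])) %% 4L))
}

toy_journals <- function(n_journals = 3) {
  tibble::tibble(journal = sprintf("J%d", seq_len(n_journals)),
                 impact_factor = c(10, 2.5, 1.081, 7, 3)[seq_len(n_journals)])
}

random_panel <- function(n_fields, n_journals, n_years, max_count = 10) {
  tidyr::expand_grid(field = sprintf("f%02d", seq_len(n_fields)),
                     journal = sprintf("J%02d", seq_len(n_journals)),
                     year = 2000L + seq_len(n_years)) |>
    dplyr::mutate(count = sample(0:max_count, dplyr::n(), replace = TRUE))
}

random_journals <- function(n_journals) {
  tibble::tibble(journal = sprintf("J%02d", seq_len(n_journals)),
                 impact_factor = runif(n_journals, 0.5, 45))
}

# oracle: triple-loop AII aggregation straight from the definition
aii_oracle <- function(panel, journals) {
  fields <- sort(unique(panel$field))
  years <- sort(unique(panel$year))
  out <- list()
  for (f in fields) for (y in years) {
    total <- 0
    for (j in journals$journal) {
      n <- panel$count[panel$field == f & panel$journal == j & panel$year == y]
      total <- total + sum(n) * journals$impact_factor[journals$journal == j]
    }
    out[[length(out) + 1L]] <- tibble::tibble(field = f, year = y, aii = total)
  }
  dplyr::bind_rows(out)
}

# oracle: polynomial least squares by explicit normal equations
polyfit_oracle <- function(t, y, degree) {
  X <- outer(as.numeric(t), 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# oracle: one-sided binomial tail by explicit summation
binom_tail_oracle <- function(matches, trials, p0) {
  sum(stats::dbinom(matches:trials, trials, p0))
}
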
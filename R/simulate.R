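#' Configuration for the synthetic publication corpus
#'
#' Bundles and validates the parameters of the seeded corpus generator. The
#' defaults emulate the study design the pipeline targets: 79 fields tracked
#' across 30 journals for 10 contiguous years, impact factors spanning
#' 1.081-44.405 with both endpoints present, small Poisson article counts,
#' and a mix of per-field trend regimes. Growth and burst magnitudes bracket
#' fold jumps observed in real field histories (roughly 5- to 25-fold
#' one-year spikes for bursting topics).
#'
#' @param n_fields Number of fields (default 79).
#' @param n_journals Number of journals (default 30).
#' @param years Contiguous integer year range (default `2008:2017`).
#' @param seed Integer RNG seed; identical configs give identical corpora.
#' @param if_range Length-2 positive `(low, high)` impact-factor range
#'   (default `c(1.081, 44.405)`); both endpoints are forced into the draw so
#'   the derived zero-substitution constant equals `low`.
#' @param regime_mix Named proportions over
#'   `c("stationary", "emerging", "burst", "declining")`, summing to 1.
#' @param base_rate Mean articles per (field, journal, year) before the
#'   regime multiplier (default 1.5 — most field-journal-year cells hold
#'   counts of 0-10).
#' @param growth_factor Per-year rate multiplier for emerging fields
#'   (default 1.6).
#' @param burst_multiplier One-year rate spike for burst fields (default 25).
#' @param decay_factor Per-year multiplier for declining fields (default 0.6).
#' @param noise `"poisson"` (default) for Poisson counts, or `"none"` for the
#'   noiseless variant (counts are the rounded expected rates) used in
#'   parameter-recovery checks.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_fields = 79, n_journals = 30, years = 2008:2017,
                       seed = 1,
                       if_range = c(1.081, 44.405),
                       regime_mix = c(stationary = 0.55, emerging = 0.20,
                                      burst = 0.15, declining = 0.10),
                       base_rate = 1.5, growth_factor = 1.6,
                       burst_multiplier = 25, decay_factor = 0.6,
                       noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (!is_whole(n_fields) || n_fields < 1) stop_config("`n_fields` must be a positive integer.")
  if (!is_whole(n_journals) || n_journals < 1) stop_config("`n_journals` must be a positive integer.")
  if (length(years) < 2L || !identical(as.integer(years), seq(min(years), max(years)))) {
    stop_config("`years` must be a contiguous ascending integer range of length >= 2.")
  }
  if (length(if_range) != 2L || if_range[1] <= 0 || if_range[1] > if_range[2]) {
    stop_config("`if_range` must be positive with low <= high.")
  }
  regimes <- c("stationary", "emerging", "burst", "declining")
  if (!setequal(names(regime_mix), regimes) || any(regime_mix < 0) ||
      abs(sum(regime_mix) - 1) > 1e-8) {
    stop_config("`regime_mix` must be named proportions over stationary/emerging/burst/declining summing to 1.")
  }
  if (base_rate < 0) stop_config("`base_rate` must be >= 0.")
  if (growth_factor <= 1) stop_config("`growth_factor` must be > 1.")
  if (burst_multiplier <= 1) stop_config("`burst_multiplier` must be > 1.")
  if (decay_factor <= 0 || decay_factor >= 1) stop_config("`decay_factor` must be in (0, 1).")
  structure(
    list(n_fields = as.integer(n_fields), n_journals = as.integer(n_journals),
         years = as.integer(years), seed = as.integer(seed),
         if_range = as.numeric(if_range),
         regime_mix = regime_mix[regimes],
         base_rate = base_rate, growth_factor = growth_factor,
         burst_multiplier = burst_multiplier, decay_factor = decay_factor,
         noise = noise),
    class = "sim_config")
}

# impact factors: log-uniform (right-skewed on the linear scale), with the
# range endpoints forced so min(IF) == if_range[1] exactly
sim_ifs <- function(config) {
  n <- config$n_journals
  lo <- config$if_range[1]; hi <- config$if_range[2]
  ifs <- exp(runif(n, log(lo), log(hi)))
  ifs[which.min(ifs)] <- lo
  if (n > 1L) ifs[which.max(ifs)] <- hi
  tibble::tibble(journal = sprintf("journal_%02d", seq_len(n)),
                 impact_factor = ifs)
}

#' Simulate a journal table
#'
#' Draws `n_journals` impact factors from a right-skewed (log-uniform)
#' distribution over `if_range`, forcing both endpoints into the sample so
#' the minimum equals `if_range[1]` exactly (and hence
#' [derive_sub_constant()] on the simulated table returns it).
#'
#' @param config A [sim_config()].
#' @return A journal-table tibble (`journal`, `impact_factor`).
#' @export
simulate_journals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_ifs(config)
}

#' Simulate a publication-count panel with planted trend regimes
#'
#' Generates a complete (field, journal, year) count panel plus the ground
#' truth behind it. Each field is assigned a regime; its expected per-journal
#' article rate over years \eqn{y_1..y_n} is
#' \describe{
#'   \item{stationary}{constant `base_rate`;}
#'   \item{emerging}{`base_rate * growth_factor^(y - y1)`;}
#'   \item{burst}{constant with one randomized year at
#'     `burst_multiplier * base_rate` (burst years are scattered across
#'     fields so spikes do not coincide);}
#'   \item{declining}{`base_rate * decay_factor^(y - y1)`.}
#' }
#' Counts are drawn independently per (field, journal, year) as
#' Poisson(rate), or set to the rounded rate when `noise = "none"`. Journals
#' are simulated from the same seed, so `simulate_panel(cfg)$journals` equals
#' `simulate_journals(cfg)`.
#'
#' @param config A [sim_config()].
#' @return A `sim_corpus` list: `panel` (complete count-panel tibble),
#'   `journals` (journal table), `truth` (per-field tibble `field`, `regime`,
#'   `rate_param` — the growth/burst/decay parameter or 1 for stationary —
#'   and `burst_year`, with the year range attached as attribute `years`),
#'   and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  journals <- sim_ifs(config)

  years <- config$years
  n_y <- length(years)
  fields <- sprintf("field_%03d", seq_len(config$n_fields))

  # regime counts from the mix, largest-remainder rounding to sum exactly
  raw <- config$regime_mix * config$n_fields
  n_reg <- floor(raw)
  rem <- config$n_fields - sum(n_reg)
  if (rem > 0) {
    top_up <- order(raw - n_reg, decreasing = TRUE)[seq_len(rem)]
    n_reg[top_up] <- n_reg[top_up] + 1
  }
  regime <- sample(rep(names(config$regime_mix), times = n_reg))

  burst_year <- ifelse(
    regime == "burst",
    sample(years[-1], config$n_fields, replace = TRUE),
    NA_integer_)
  rate_param <- dplyr::case_when(
    regime == "emerging" ~ config$growth_factor,
    regime == "burst" ~ config$burst_multiplier,
    regime == "declining" ~ config$decay_factor,
    TRUE ~ 1)
  truth <- tibble::tibble(field = fields, regime = regime,
                          rate_param = rate_param,
                          burst_year = as.integer(burst_year))
  attr(truth, "years") <- years

  panel <- purrr::pmap_dfr(truth, function(field, regime, rate_param, burst_year) {
    lam <- field_rates(config, regime, rate_param, burst_year)
    counts <- if (config$noise == "poisson") {
      rpois(config$n_journals * n_y, rep(lam, each = config$n_journals))
    } else {
      rep(round(lam), each = config$n_journals)
    }
    tibble::tibble(field = field,
                   journal = rep(journals$journal, times = n_y),
                   year = rep(years, each = config$n_journals),
                   count = as.integer(counts))
  })

  structure(list(panel = panel, journals = journals, truth = truth,
                 config = config),
            class = "sim_corpus")
}

# expected per-journal rate per year for one field
field_rates <- function(config, regime, rate_param, burst_year) {
  years <- config$years
  t <- years - years[1]
  switch(regime,
    stationary = rep(config$base_rate, length(years)),
    emerging = config$base_rate * rate_param^t,
    declining = config$base_rate * rate_param^t,
    burst = ifelse(years == burst_year, config$base_rate * rate_param,
                   config$base_rate))
}

#' Noiseless fold-change trajectory implied by a field's regime
#'
#' The fold change of the expected rate model, i.e. the ratio of consecutive
#' years' rates: 1 everywhere for a stationary field, the growth factor for
#' an emerging field, the decay factor for a declining field, and for a burst
#' field the multiplier at the burst year, its reciprocal the year after, and
#' 1 elsewhere.
#'
#' @param truth Ground-truth tibble from [simulate_panel()] (carries the year
#'   range as attribute `years`).
#' @param field Field name present in `truth`.
#' @return A tibble with columns `year` (all years but the first) and
#'   `expected_delta` (positive double).
#' @export
expected_delta_trajectory <- function(truth, field) {
  row <- truth[truth$field == field, , drop = FALSE]
  if (nrow(row) == 0L) stop_lookup(sprintf("Unknown field '%s' in ground truth.", field))
  years <- attr(truth, "years")
  if (is.null(years)) stop_validation("`truth` is missing its 'years' attribute.")
  d <- switch(row$regime,
    stationary = rep(1, length(years) - 1L),
    emerging = rep(row$rate_param, length(years) - 1L),
    declining = rep(row$rate_param, length(years) - 1L),
    burst = {
      v <- rep(1, length(years) - 1L)
      at <- match(row$burst_year, years[-1])
      if (!is.na(at)) v[at] <- row$rate_param
      if (!is.na(at) && at < length(v)) v[at + 1L] <- 1 / row$rate_param
      v
    })
  tibble::tibble(year = years[-1], expected_delta = d)
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf(
    "<sim_corpus> %d fields x %d journals x %d years (%d-%d), %s counts, seed %d\n",
    x$config$n_fields, x$config$n_journals, length(x$config$years),
    min(x$config$years), max(x$config$years), x$config$noise, x$config$seed))
  print(table(x$truth$regime))
  invisible(x)
}
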
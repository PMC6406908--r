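test_that("simulation config validates its parameters", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_fields, 79L)
  expect_equal(cfg$n_journals, 30L)
  expect_equal(cfg$years, 2008:2017)
  expect_equal(cfg$if_range, c(1.081, 44.405))
  expect_equal(sum(cfg$regime_mix), 1)

  expect_error(sim_config(years = c(2008, 2010)), class = "bibtrend_config_error")
  expect_error(sim_config(regime_mix = c(stationary = 0.5, emerging = 0.2,
                                         burst = 0.2, declining = 0.2)),
               class = "bibtrend_config_error")
  expect_error(sim_config(growth_factor = 0.9), class = "bibtrend_config_error")
  expect_error(sim_config(if_range = c(0, 10)), class = "bibtrend_config_error")
})

test_that("simulated journals span the IF range with forced endpoints", {
  cfg <- sim_config(seed = 5)
  journals <- simulate_journals(cfg)
  expect_equal(nrow(journals), 30L)
  expect_equal(min(journals$impact_factor), 1.081)
  expect_equal(max(journals$impact_factor), 44.405)
  expect_equal(derive_sub_constant(journals), 1.081)
  expect_identical(journals, simulate_journals(cfg))

  one <- simulate_journals(sim_config(n_journals = 1, seed = 5))
  expect_equal(one$impact_factor, 1.081)
})

test_that("simulated panels are reproducible and structurally complete", {
  cfg <- sim_config(n_fields = 12, n_journals = 6, years = 2010:2015, seed = 33)
  corpus <- simulate_panel(cfg)
  expect_equal(nrow(corpus$panel), 12 * 6 * 6)
  expect_true(all(corpus$panel$count >= 0))
  expect_equal(nrow(corpus$truth), 12)
  expect_identical(corpus$panel, simulate_panel(cfg)$panel)
  expect_identical(corpus$journals, simulate_journals(cfg))

  # byte-identical CSV on regeneration
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_count_panel(corpus$panel, f1)
  write_count_panel(simulate_panel(cfg)$panel, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a different seed gives different counts
  other <- simulate_panel(sim_config(n_fields = 12, n_journals = 6,
                                     years = 2010:2015, seed = 34))
  expect_false(identical(corpus$panel$count, other$panel$count))
})

test_that("a zero base rate exercises the substitution path end to end", {
  cfg <- sim_config(n_fields = 4, n_journals = 3, years = 2010:2014,
                    seed = 2, base_rate = 0,
                    regime_mix = c(stationary = 1, emerging = 0,
                                   burst = 0, declining = 0))
  corpus <- simulate_panel(cfg)
  expect_true(all(corpus$panel$count == 0L))
  d <- delta_aii(compute_aii(corpus$panel, corpus$journals))
  expect_equal(unique(d$substituted), "both")
  expect_equal(unique(d$delta_aii), 1)
})

test_that("expected fold-change trajectories follow the planted regimes", {
  cfg <- sim_config(n_fields = 40, n_journals = 4, years = 2010:2015, seed = 44,
                    regime_mix = c(stationary = 0.25, emerging = 0.25,
                                   burst = 0.25, declining = 0.25),
                    growth_factor = 2, burst_multiplier = 10, decay_factor = 0.5)
  truth <- simulate_panel(cfg)$truth

  stat_f <- truth$field[truth$regime == "stationary"][1]
  expect_equal(expected_delta_trajectory(truth, stat_f)$expected_delta, rep(1, 5))

  emer_f <- truth$field[truth$regime == "emerging"][1]
  expect_equal(expected_delta_trajectory(truth, emer_f)$expected_delta, rep(2, 5))

  decl_f <- truth$field[truth$regime == "declining"][1]
  expect_equal(expected_delta_trajectory(truth, decl_f)$expected_delta, rep(0.5, 5))

  burst_rows <- truth[truth$regime == "burst", ]
  b <- burst_rows[1, ]
  traj <- expected_delta_trajectory(truth, b$field)
  expect_equal(traj$expected_delta[traj$year == b$burst_year], 10)
  if (b$burst_year < max(cfg$years)) {
    expect_equal(traj$expected_delta[traj$year == b$burst_year + 1], 0.1)
  }
  expect_equal(traj$expected_delta[!traj$year %in% (b$burst_year + 0:1)],
               rep(1, sum(!traj$year %in% (b$burst_year + 0:1))))

  expect_error(expected_delta_trajectory(truth, "ghost"),
               class = "bibtrend_lookup_error")
})

test_that("realized fold changes of emerging fields converge to the growth factor", {
  cfg <- sim_config(n_fields = 200, n_journals = 10, years = 2011:2013,
                    seed = 55, base_rate = 30, growth_factor = 1.6,
                    regime_mix = c(stationary = 0, emerging = 1,
                                   burst = 0, declining = 0))
  corpus <- simulate_panel(cfg)
  d <- delta_aii(compute_aii(corpus$panel, corpus$journals))
  per_field <- d$delta_aii[d$year == 2012]
  se <- stats::sd(per_field) / sqrt(length(per_field))
  expect_lt(abs(mean(per_field) - 1.6), 3 * se)
})

test_that("the pipeline recovers planted growth fields into the top-k", {
  cfg <- sim_config(n_fields = 20, n_journals = 5, years = 2008:2017,
                    seed = 66, base_rate = 50, growth_factor = 1.6,
                    regime_mix = c(stationary = 0.75, emerging = 0.25,
                                   burst = 0, declining = 0),
                    noise = "none")
  corpus <- simulate_panel(cfg)
  planted <- sort(corpus$truth$field[corpus$truth$regime == "emerging"])
  d <- delta_aii(compute_aii(corpus$panel, corpus$journals))
  fc <- forecast_fields(d, end_year = 2015, degree = 1, horizon = 1,
                        top_k = length(planted))
  expect_equal(sort(fc$top_k_fields), planted)
})
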
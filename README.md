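# bibtrend

Forecasting emerging research fields from journal-level publication counts.

`bibtrend` is for bibliometricians and domain scientists who want an
objective, reproducible answer to "which topics in my field are about to take
off?" using nothing but per-journal article counts and journal impact
factors. It implements an impact-weighted trend index, a polynomial
extrapolation forecaster, and a sliding-window backtest with exact binomial
significance against a pick-at-random baseline — plus a seeded synthetic
corpus generator so the whole pipeline can be exercised and validated with no
database access.

## The model

For a field *f*, journal *j* and year *y*, with *N* the number of articles
and *IF<sub>j</sub>* the journal's impact factor:

- **Annual impact**: `AI(f, j, y) = N(f, j, y) × IF_j` — article count
  weighted by journal prominence.
- **Annual impact index**: `AII(f, y) = Σ_j AI(f, j, y)` — the field's
  impact-weighted publication mass across all tracked journals.
- **Fold change**: `ΔAII(f, y) = AII(f, y) / AII(f, y − 1)` — the field's
  momentum, independent of its absolute size, so a small emerging topic can
  outrank an established giant. A zero AII is replaced by a pseudo-count
  (default 1.081 — the score of a single article in the lowest-impact-factor
  tracked journal) so fold changes stay finite and positive.
- **Forecast**: a degree-1/2/3 least-squares polynomial is fitted to each
  field's fold changes over a 5-year window and evaluated 1–3 years past the
  window; fields are ranked by predicted fold change and the top 20 declared
  "hot".
- **Backtest**: over every window whose target year is still observed, the
  predicted top-k is intersected with the actual top-k (rank-agnostic);
  pooled matches over `top_k × n_windows` slots get a one-sided exact
  binomial p-value against the coincidence probability `p0 = top_k /
  n_fields` (20/79 ≈ 25.3% in the default design). Point accuracy is the
  share of horizon-1 predictions within ±1.0 fold of the actual value.

## Worked example

```r
library(bibtrend)

annual_impact(6, 40.137)
#> [1] 240.822          # 6 articles in a journal with impact factor 40.137

cfg    <- sim_config(seed = 42)            # 79 fields x 30 journals x 2008-2017
corpus <- simulate_panel(cfg)              # counts + journals + ground truth
aii    <- compute_aii(corpus$panel, corpus$journals)
delta  <- delta_aii(aii)                   # fold changes, zeros substituted

fc <- forecast_fields(delta, end_year = 2015, degree = 1, horizon = 2, top_k = 20)
head(tidy(fc), 5)
#> # A tibble: 5 × 5
#>   field     predicted_delta_aii  rank in_top_k nonpositive
#>   <chr>                   <dbl> <int> <lgl>    <lgl>
#> 1 field_022               15.9      1 TRUE     FALSE
#> 2 field_043                4.94     2 TRUE     FALSE
#> 3 field_042                4.68     3 TRUE     FALSE
#> 4 field_037                3.94     4 TRUE     FALSE
#> 5 field_064                3.73     5 TRUE     FALSE

run_backtest(delta, degree = 1, window_length = 5, horizons = 1:3, top_k = 20)
#> <trend_backtest> degree-1 polynomial, window 5, top-20 of 79 fields (p0 = 25.3%)
#> Point accuracy (horizon 1, +/- 1.0 fold): 82.6% (261/316)
#> # A tibble: 3 × 6
#>   horizon windows matches trials accuracy    p_value
#>     <int>   <int>   <int>  <int>    <dbl>      <dbl>
#> 1       1       4      39     80    0.488 0.00000544
#> 2       2       3      27     60    0.45  0.000731
#> 3       3       2      19     40    0.475 0.00200
```

`field_022` is predicted to grow ~16-fold two years past the fitting window —
with this seed it is one of the planted burst fields (`corpus$truth`). The
backtest says the linear forecaster's top-20 overlaps the realized top-20 at
45–49% across horizons, well above the 25.3% expected from picking 20 of 79
fields at random (all pooled p-values < 0.05). Point predictions land within
±1 fold for 83% of field-windows. `autoplot()` on either object draws the
corresponding figure, and `tidy()`/`glance()` return the tables.

Real PubMed-style inputs enter through `read_journal_table()` (CSV
`name,impact_factor`) and `read_count_panel()` (long CSV
`field,journal,year,count` or nested JSON; absent rows mean zero counts);
`build_pubmed_query()` renders the exact search-window command used to
collect a count for one (field, journal, year).

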
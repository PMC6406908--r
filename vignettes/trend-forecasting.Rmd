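---
title: "Forecasting emerging research fields from impact-weighted publication counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting emerging research fields from impact-weighted publication counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bibtrend)
```

## The problem and the index

Detecting which research topics are gaining momentum is usually done by
expert impression, which is slow and biased. `bibtrend` works instead from a
fully mechanical signal: how many articles each field keyword placed in each
of a fixed set of prominent journals, year by year. Raw counts alone would
reward big journals and big fields, so two corrections are built in.

First, counts are weighted by journal prominence. The **annual impact** of a
field in one journal-year is `AI = N × IF`, the article count times the
journal's impact factor, and the **annual impact index** `AII` sums this over
all tracked journals. Six articles in a journal with impact factor 40.137
score `r annual_impact(6, 40.137)`; six in a low-tier journal score a
fraction of that. The impact factor is a static per-run snapshot: one
Journal Citation Reports edition is applied to every panel year, so the index
measures where articles land, not how citation metrics drift.

Second, fields are compared on **fold change**, not level:
`ΔAII(y) = AII(y) / AII(y − 1)`. An established field with an enormous AII
and a flat trajectory should not outrank a small topic that tripled. Fold
changes equalize fields of different breadth and maturity — the quantity
forecast and ranked is momentum.

### Zero substitution

A field can have a zero AII year (no articles anywhere), making the ratio
undefined or zero. Any zero value — numerator or denominator — is replaced
by a pseudo-count before dividing. Its default, 1.081, is the smallest score
the index can award: one article in the lowest-impact-factor tracked journal
(`derive_sub_constant()` recomputes it from any journal table). Substituting
both positions, rather than the denominator only, keeps ΔAII finite,
positive and symmetric, and makes a 0 → 0 transition read as "no change"
(fold 1) rather than an artefactual spike. Every substitution is recorded in
the output (`substituted` column), so the denominator-only variant can be
audited after the fact. The constant is a tunable parameter; analyses of a
different journal set should derive it from their own table.

## Forecasting

For each field, the last `window_length = 5` fold changes are fitted with a
least-squares polynomial of degree 1, 2 or 3 and the fitted curve is
evaluated 1–3 years past the window. Time is indexed 1..5 inside the window;
calendar years map onto that affinely, which changes the coefficients but
not the extrapolated values. The solve uses the QR factorization of the
Vandermonde basis via `stats::lm.fit`; the explicit normal-equations solve
exists only as an independent oracle in the test suite. Five points fit a
cubic with one residual degree of freedom — the window is deliberately
short, because topic momentum is non-stationary and old history misleads.

Fields are ranked by predicted fold change, descending, with lexicographic
tie-breaking so the ranking is a deterministic function of the data, and the
top `top_k = 20` are declared the predicted hot fields. Extrapolation can
undershoot below zero, which no true fold change can; such values are kept
and ranked as-is (they are honest model output and always rank last) but
flagged in a `nonpositive` column.

Degree 1 is the default and the recommended choice: in backtests the
quadratic and cubic fits chase noise in 5-point windows and extrapolate
erratically, so the linear fit is the one to report.
No averaging across degrees is done; each is evaluated on its own.

## Backtesting

`run_backtest()` validates the forecaster on held-out history. Every sliding
window whose target year is still observed contributes:

- **Point accuracy** ("accuracy A"): the fraction of horizon-1 predictions
  within `tolerance = 1.0` of the actual fold change, pooled over all fields
  and windows. The tolerance is read in absolute fold units
  (|pred − actual| ≤ 1.0), not as a ratio — the compared quantity is itself
  already a fold change.
- **Top-k accuracy** (horizons 1–3): the rank-agnostic intersection of the
  predicted and actual top-k field sets, pooled across windows into
  `top_k × n_windows` trials per horizon.

Pooled match counts get a one-sided exact binomial p-value
(`P(X ≥ matches)`, `stats::pbinom`) against the coincidence probability
`p0 = top_k / n_fields` — the expected match rate of picking top-k fields
uniformly at random (20/79 ≈ 25.3% under the default design). One-sided,
because the question is whether prediction beats coincidence; the
significance threshold in reporting is 0.05, with no multiple-testing
correction across the three degrees. Per-window match counts and p-values
are also kept in the result for transparency.

## The synthetic corpus

`simulate_panel()` generates the study design the pipeline targets — 79
fields × 30 journals × 10 contiguous years — with planted, recoverable
structure:

| Parameter | Default | Meaning |
|---|---|---|
| `if_range` | 1.081–44.405 | impact factors, log-uniform (right-skewed), endpoints forced |
| `base_rate` | 1.5 | mean articles per field-journal-year (cells mostly 0–10) |
| `regime_mix` | .55/.20/.15/.10 | stationary / emerging / burst / declining fields |
| `growth_factor` | 1.6 | per-year rate multiplier of emerging fields |
| `burst_multiplier` | 25 | one-year spike of burst fields |
| `decay_factor` | 0.6 | per-year multiplier of declining fields |
| `noise` | `"poisson"` | count noise; `"none"` rounds the expected rates |

Counts are independent Poisson draws given the field's rate trajectory — the
minimal defensible noise model for small hit-count tallies (an
overdispersed variant would be the natural extension). Burst years are
randomized per field so spikes do not coincide; growth and decay run from
the first panel year, so an emerging field's noiseless fold-change
trajectory is constant at `growth_factor` (and a burst field's is the
multiplier at the burst year, its reciprocal the year after, 1 elsewhere —
`expected_delta_trajectory()` returns these). The growth and burst defaults
bracket fold jumps observed in real field histories, where one-year spikes
of roughly 5- and 25-fold occur. Everything is driven by one seed:
identical configurations give byte-identical panels.

What the generator does *not* emulate: topical correlation between fields,
journal-level specialization (every journal shares a field's rate), drifting
impact factors, and keyword ambiguity. Passing tests on this corpus
therefore demonstrate that the machinery is correct and that planted trends
of realistic magnitude are recoverable — not that real literature is this
well-behaved.

## Numerical and design notes

- **Degenerate inputs.** Absent (field, journal, year) rows are zero counts,
  not errors — a search engine returning zero hits writes no row. An
  all-zero field exercises the substitution path and yields a flat ΔAII of 1.
  Duplicated time indices or too few points are fit errors; a backtest on a
  span shorter than `window_length + min(horizon)` fails with the minimum
  span named.
- **Precision.** AII and fold changes are carried at full double precision;
  3-decimal figures in displays are rounding only.
- **Tie-breaks.** Both predicted and actual rankings break ties
  lexicographically by field name, so top-k sets are reproducible across
  platforms and input orderings.
- **Mean reversion at horizon 1.** On a pure-noise (all-stationary) corpus,
  the horizon-1 top-k overlap is systematically *below* the coincidence rate:
  the window-end AII enters both the prediction (numerator of the last fold
  change in the window) and the target (denominator of the next fold
  change), so a field that spiked up is predicted high yet reverts low.
  Calibration against the `k/n` baseline is therefore checked at horizon 2,
  where the fitting window and the target share no AII year and the pooled
  overlap of a null corpus is binomial at `p0`. On real, trending data this
  anticorrelation is diluted by signal, but horizon-1 top-k accuracies
  should be read with it in mind.
- **Problem sizes in the test suite.** Property checks run on panels up to
  10 × 10 × 10 with a 1000-window least-squares oracle comparison; the null
  calibration uses an all-stationary corpus spanning 61 years (55 sliding
  windows, 1100 pooled trials), sized so the binomial band is tight enough
  to be informative. These are the package's chosen sizes for a thorough
  yet quick default run.
- **Network independence.** The pipeline never touches a live database; the
  query builder only renders the exact search-window command
  (`build_pubmed_query("pilocytic astrocytoma", "Nature", 2015)`) so that a
  harvested corpus can be reproduced or audited externally. Broad keywords
  can be "directed" by conjoining an auxiliary disambiguation term (default
  `"brain tumor"`), rendered as `((keyword) AND (aux))` — chosen for
  unambiguous boolean grouping.

## Limitations

The index inherits the impact factor's known pathologies (field-size
dependence, review-journal inflation) and treats all articles in a journal
as equal. Keyword hit counts conflate homonyms unless directed. The
forecaster is a point predictor with no uncertainty intervals, and
polynomial extrapolation of 5-point windows is intentionally simple —
degree 2 and 3 should be treated as sensitivity analyses around the linear
default rather than competitors.
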
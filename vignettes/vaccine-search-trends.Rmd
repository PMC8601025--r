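---
title: "Classifying and trending COVID-19 vaccine search queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and trending COVID-19 vaccine search queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxquery)
library(dplyr)
```

## The problem

When a population starts searching the web for a vaccine, the *language* of
those searches carries public-health signal: queries naming a pharmacy chain
suggest active intent to get vaccinated, queries about side effects or
vaccine myths suggest hesitancy or concern. vaxquery implements an
infodemiology pipeline for exactly this kind of analysis of search-engine
query logs restricted to COVID-19 vaccine searches:

1. a **rules-based multi-label classifier** that assigns each query to one
   or more of five categories — availability, manufacturer, side
   effects/safety, myths/conspiracy beliefs, and a general/other fallback —
   plus a *pharmacy* subcategory of availability;
2. **weekly trend statistics**: volume-weighted category proportions per
   7-day block and an ordinary-least-squares time trend per category;
3. **relative search volume (RSV)** normalization of count series to the
   0–100 scale used by public search-interest tools;
4. an **evaluation harness** (per-category precision/recall against gold
   labels, and coverage);
5. a **synthetic query-log generator**, because real search-engine query
   logs are proprietary: it produces seeded, gold-labeled logs with the
   statistical structure the analysis assumes, so every stage of the
   pipeline is testable end to end.

## The classifier

Query text is normalized before any matching: lower-cased, punctuation
(including hyphens and ampersands) replaced by spaces, digit suffixes split
off "covid" (so `covid19` and `covid-19` both become the tokens `covid`,
`19`), and intra-word apostrophes preserved. A curated spelling-variant
table is then applied token-wise (`vaccinations` → `vaccine`, `phizer` →
`pfizer`, ...). Matching itself is deliberately conservative: a lexicon
pattern fires only when its token sequence appears *contiguously* in the
normalized query (`j&j` normalizes to the bigram `j j` and is matched as
such). There is no stemming and no fuzzy matching by default; an optional
edit-distance-1 mode (`fuzzy = TRUE`) canonicalizes unknown tokens that are
uniquely one edit from a vocabulary word, but it is off because exact
matching is what makes near-perfect precision plausible on this domain.

Two rules give the category set its shape:

* a query receives **every** specific category with a firing pattern
  (multi-label; a query naming both a manufacturer and a pharmacy counts in
  both categories),
* `general_other` is an **exclusive fallback**: it is assigned exactly when
  no specific pattern fires, so classification is total and the residual
  "other" mass lives inside the general category.

```{r classify}
lex <- default_lexicon()
classify_queries(
  tibble::tibble(query = c(
    "Pfizer covid vaccine CVS", "covid vaccine near me",
    "does covid vaccine change dna", "covid vaccine"
  )),
  lex
) |>
  mutate(categories = sapply(categories, paste, collapse = "+")) |>
  select(query, categories, pharmacy)
```

The shipped lexicon (`default_lexicon()`, versioned, JSON on disk) is a
frozen reconstruction of the study vocabulary: all 50 US state names and
common abbreviations, availability phrases, a pharmacy-chain list,
manufacturer names, side-effect terms, and the five recurring myth themes
(infertility, DNA, microchips, 5G, catching COVID from the vaccine). It is
an explicit input everywhere, so users can extend or replace it; adding a
pattern to one category can never remove a category from any query nor
disturb other categories' matches (a property the tests enforce).

The study-universe filter is separate from classification:
`filter_study_queries()` keeps queries containing both a covid-equivalent
and a vaccine-equivalent token. We treat `coronavirus` as a covid
equivalent and `vaccination`/`vaccinated`/`vax` as vaccine equivalents; the
filter is applied first in the pipeline, classification second, so
off-universe but classifiable queries (e.g. `pfizer vaccine`) still
classify when fed directly.

## Weekly proportions and trends

`weekly_shares()` partitions the study window into consecutive 7-day blocks
anchored at the start date and drops a trailing partial block — a 75-day
window therefore yields exactly 10 weekly points. We chose start-anchored
blocks over ISO calendar weeks because the trend analysis treats "week
number since study start" as the regressor. Shares are **volume-weighted**:
each query contributes its daily count, not one vote per distinct string,
because a truncated top-k query log is a volume sample. With 10 weekly
points, each per-category OLS fit has `df = n − 2 = 8`.

`fit_trend()` performs the OLS fit (delegating to `stats::lm`) and reports
slope, intercept, R², df and the two-sided slope t-test p-value; shares are
rescaled to percent by default in `fit_category_trends()` so the slope
reads in percentage points per week. No multiple-testing correction is
applied: per-category p-values are reported raw. Degenerate inputs are
handled explicitly: a constant response yields `beta = 0`, `r_squared = 0`
and a degenerate flag (not an error, because flat category series are
legitimate), while a constant predictor or fewer than 3 points is an error.

```{r trends}
cfg <- study_scenario(queries_per_day = 5000, seed = 42)
syn <- generate_log(cfg)
res <- syn$records |>
  filter_study_queries(lex) |>
  classify_queries(lex) |>
  weekly_shares(cfg$start_date, cfg$start_date + 69)
fit_category_trends(res)
```

`rsv_normalize()` implements the 0–100 relative-search-volume rescaling:
jointly across series (shared global peak, so series stay comparable) or
per series. Values keep full floating precision by default; `round = TRUE`
mimics the integer output of public tools. The transformation is scale
invariant — multiplying all counts by any positive constant leaves RSV
unchanged — and after joint normalization exactly the global-peak points
equal 100.

## Evaluation

`precision_recall()` scores one-vs-rest per category (the pharmacy flag as
its own binary label): per-query TP/FP/FN counts, precision `TP/(TP+FP)`
and recall `TP/(TP+FN)`. A 0/0 ratio is reported as `NA` with an explicit
`*_defined = FALSE` flag — silent 0-or-1 conventions corrupt comparisons.
Counting is per record; multi-label sets are scored per category, not as
exact set matches, because per-category precision/recall is the quantity of
scientific interest here.

`specific_coverage()` is the "how much of the volume does the lexicon
actually explain" statistic: the volume-weighted fraction of queries that
either carry a specific category or whose whole normalized text equals one
of the explicit bare general forms (`covid vaccine`, `coronavirus vaccine`,
...). The complement is residual "other" mass. Whether bare general queries
count as "classified" is genuinely ambiguous in this kind of analysis; we
count them, list the forms explicitly in the lexicon, and expose the list
as an argument so the opposite convention is one call away.

## The synthetic generator

`generate_log()` emulates the structure of a truncated search-engine query
log for this domain:

* **Zipfian popularity.** Within each category universe, distinct query
  strings get weights proportional to `rank^(-s)` (`zipf_weights()`,
  default `s = 1`), reproducing the heavy concentration of volume in a
  small head of common queries.
* **Linear share trajectories.** Each category's expected share of daily
  volume interpolates linearly between a start and an end value, evaluated
  at the day's week index (constant within a week) — matching the linear
  trend model the analysis fits. Configured shares partition volume each
  week; the general share is the remainder.
* **A pharmacy sub-trajectory** inside availability, specified as a share
  of *total* volume so it is directly comparable to the measured pharmacy
  share.
* **Explicit multi-label mass.** A configurable fraction (default 5%) of
  pharmacy volume uses composite templates that also name a manufacturer,
  so those queries carry the gold set {availability, manufacturer}. Because
  overlap enters only through this explicit channel, every expected share
  stays analytically known (`expected_shares()`): manufacturer's measured
  expectation is its configured share plus `composite_rate ×
  pharmacy(week)`; all other categories equal their configured
  trajectories.
* **Template grammars over the shipped lexicon.** Query strings are built
  from per-category templates ("covid vaccine {state}", "{pharmacy} covid
  vaccine appointment", ...), which guarantees the gold label equals the
  grammar category and every generated query passes the study filter. With
  zero label noise the shipped classifier must therefore score precision =
  recall = 1 on generator output — the end-to-end consistency test.
* **Label noise** flips a record's gold set, with probability ε, to one
  uniformly chosen different category. When per-category record counts are
  balanced, flipped-in and flipped-out mass cancel and per-category recall
  converges to exactly 1 − ε; the noise tests use a balanced flat scenario
  for this reason, and with unbalanced categories the relation is only
  approximate.
* **Determinism.** Daily counts are exact multinomial draws
  (`stats::rmultinom`) seeded from per-day, per-purpose substreams of the
  master seed, so identical configurations reproduce byte-identical logs
  and changing, say, the noise rate does not perturb the volume draws.

`study_scenario()` is the preset used throughout the tests and the
acceptance script: 10 weeks from 2021-01-01 at 50,000 queries/day,
availability flat at 62% with pharmacy rising 5.9% → 27.2%, manufacturer
flat at 10.4%, side effects falling 5.7% → 4.2%, myths falling 0.4% →
0.1%. Where only endpoints are known for a trajectory, the preset is linear
between them by construction.

What the generator does **not** emulate: real session behavior,
reformulations, geographic or device mix, autocorrelated day-to-day noise,
or bursty news-driven spikes. Passing tests on generator output therefore
demonstrate that the pipeline's statistics are correct and internally
consistent under the stated model — not that the shipped lexicon would
achieve any particular precision or coverage on real, messier query logs.

## Sizes, tolerances and other numerical choices

* Test problem sizes were chosen for statistical resolution: parameter
  recovery uses the full 50,000 queries/day preset over 20 seeds (slope
  estimates compared to configured slopes within 3 Monte-Carlo standard
  errors; sign recovery must be exact in every seed); cheaper smoke tests
  use 500–6,000 queries/day.
* Sampling-based assertions use 3-standard-error bands (multinomial or
  binomial as appropriate) under fixed seeds; analytic identities (Zipf
  mass, OLS closed form) are asserted to 1e-10–1e-12.
* `daily_topk()` breaks count ties by lexicographic query text so
  truncation is deterministic across runs.
* Weekly aggregation refuses windows with an empty retained week
  (degenerate-data error) rather than producing NaN shares.
* All dates are ISO-8601, all files UTF-8, category names serialize in a
  fixed documented order (`vax_categories`), and artifacts are written at
  full float precision so write-then-read round-trips exactly.

## Limitations

The lexicon is a faithful reconstruction of the published category
vocabulary, not the original production term lists, and the generator's
intermediate weekly values are linear interpolations between published
endpoints rather than a reconstruction of unpublished weekly data. Trend
fits are plain OLS on ≤ 10 points: no autocorrelation handling, changepoint
detection or forecasting is attempted, and none is claimed.
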
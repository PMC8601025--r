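test_that("zipf weights are normalized, strictly decreasing, analytic", {
  expect_equal(zipf_weights(2, 1), c(2 / 3, 1 / 3), tolerance = 1e-15)
  near_uniform <- zipf_weights(3, 1e-4)
  expect_equal(near_uniform, rep(1 / 3, 3), tolerance = 1e-3)
  w <- zipf_weights(1000, 1)
  expect_equal(sum(w[1:150]), harmonic(150) / harmonic(1000), tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  for (n in c(1, 10, 1e4, 1e6)) {
    expect_equal(sum(zipf_weights(n, 1)), 1, tolerance = 1e-12)
    expect_equal(sum(zipf_weights(n, 0.7)), 1, tolerance = 1e-12)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_weeks = 0), class = "vaxquery_config_error")
  expect_error(synthetic_config(zipf_exponent = 0), class = "vaxquery_config_error")
  expect_error(synthetic_config(label_noise = 1), class = "vaxquery_config_error")
  expect_error(
    synthetic_config(pharmacy = c(0.9, 0.9)), # exceeds availability
    class = "vaxquery_config_error"
  )
  expect_error(
    synthetic_config(shares = list(
      availability = c(0.8, 0.8), manufacturer = c(0.3, 0.3),
      side_effects_safety = c(0, 0), myths_conspiracy = c(0, 0)
    )),
    class = "vaxquery_config_error"
  )
  expect_error(
    synthetic_config(universe = c(availability = 10000)),
    class = "vaxquery_config_error"
  )
  # degenerate but legal: one week of zero volume gives an empty log
  empty <- generate_log(synthetic_config(n_weeks = 1, queries_per_day = 0))
  expect_equal(nrow(empty$records), 0L)
})

test_that("the study preset carries the configured endpoint shares", {
  cfg <- study_scenario()
  expect_equal(cfg$pharmacy[1], 0.059)
  expect_equal(cfg$pharmacy[2], 0.272)
  expect_equal(cfg$shares$myths_conspiracy[2], 0.001)
  expect_equal(cfg$shares$side_effects_safety, c(0.057, 0.042))
  expect_equal(cfg$n_weeks, 10L)
  # configured specific + general shares partition volume at every week
  es <- expected_shares(cfg)
  total <- with(
    es,
    availability + (manufacturer - cfg$composite_rate * pharmacy) +
      side_effects_safety + myths_conspiracy + general_other
  )
  expect_equal(total, rep(1, 10), tolerance = 1e-12)
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- synthetic_config(n_weeks = 2, queries_per_day = 500, seed = 42)
  a <- generate_log(cfg)
  b <- generate_log(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$gold, b$gold)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(a$records, f1)
  readr::write_tsv(b$records, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed perturbs the draws
  c2 <- generate_log(synthetic_config(n_weeks = 2, queries_per_day = 500, seed = 43))
  expect_false(identical(a$records, c2$records))
})

test_that("flat-share logs reproduce configured shares within multinomial error", {
  cfg <- synthetic_config(
    n_weeks = 4, queries_per_day = 20000,
    shares = list(
      availability = c(0.5, 0.5), manufacturer = c(0.2, 0.2),
      side_effects_safety = c(0.1, 0.1), myths_conspiracy = c(0.05, 0.05)
    ),
    pharmacy = c(0.2, 0.2), composite_rate = 0, seed = 99
  )
  syn <- generate_log(cfg)
  cl <- classify_queries(syn$records)
  ws <- weekly_shares(cl, cfg$start_date, cfg$start_date + 27)
  n_week <- 7 * cfg$queries_per_day
  for (cc in c("availability", "manufacturer", "side_effects_safety", "myths_conspiracy", "pharmacy")) {
    p <- expected_shares(cfg)[[cc]]
    se <- sqrt(p * (1 - p) / n_week)
    expect_true(all(abs(ws[[cc]] - p) <= 3 * se), info = cc)
  }
})

test_that("with no label noise the classifier is gold-consistent on generated logs", {
  cfg <- study_scenario(queries_per_day = 2000, seed = 5)
  syn <- generate_log(cfg)
  cl <- classify_queries(syn$records)
  rep <- precision_recall(cl, syn$gold)
  expect_true(all(rep$precision[rep$precision_defined] == 1))
  expect_true(all(rep$recall[rep$recall_defined] == 1))
  # and generated queries all pass the study inclusion filter
  expect_equal(nrow(filter_study_queries(syn$records)), nrow(syn$records))
})

test_that("per-day topk truncation inside the generator matches daily_topk", {
  cfg_full <- synthetic_config(n_weeks = 1, queries_per_day = 3000, seed = 8)
  cfg_trunc <- synthetic_config(n_weeks = 1, queries_per_day = 3000, seed = 8, topk = 25)
  full <- generate_log(cfg_full)
  trunc <- generate_log(cfg_trunc)
  expect_equal(
    dplyr::arrange(trunc$records, date, dplyr::desc(count), query),
    dplyr::arrange(daily_topk(full$records, 25), date, dplyr::desc(count), query)
  )
  expect_true(all(dplyr::count(trunc$records, date)$n <= 25))
  # gold stays aligned with retained records
  expect_equal(nrow(trunc$gold), nrow(trunc$records))
})

test_that("sampled top-k volume share matches the harmonic-sum value within sampling error", {
  cfg <- synthetic_config(
    n_weeks = 2, queries_per_day = 50000,
    shares = list(
      availability = c(0, 0), manufacturer = c(0, 0),
      side_effects_safety = c(0, 0), myths_conspiracy = c(0, 0)
    ),
    pharmacy = c(0, 0), composite_rate = 0,
    universe = c(general_other = 30), zipf_exponent = 1, seed = 21
  )
  syn <- generate_log(cfg)
  freq <- dplyr::summarise(
    dplyr::group_by(syn$records, query),
    count = sum(count), .groups = "drop"
  )
  k <- 5
  analytic <- harmonic(k) / harmonic(30)
  n_total <- sum(freq$count)
  se <- sqrt(analytic * (1 - analytic) / n_total)
  expect_equal(topk_volume_share(freq, k), analytic, tolerance = 5 * se / analytic)
  expect_equal(topk_volume_share(freq, 30), 1)
})
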
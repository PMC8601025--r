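make_classified <- function(rows) {
  # rows: list of list(date, cats, count, pharmacy)
  tibble::tibble(
    date = as.Date(vapply(rows, `[[`, character(1), "date")),
    query = paste0("q", seq_along(rows)),
    count = vapply(rows, `[[`, numeric(1), "count"),
    categories = lapply(rows, `[[`, "cats"),
    pharmacy = vapply(rows, function(r) isTRUE(r$pharmacy), logical(1))
  )
}

test_that("weekly shares are volume-weighted ratios with multi-label double counting", {
  rows <- list(
    list(date = "2021-01-01", cats = "availability", count = 60, pharmacy = TRUE),
    list(date = "2021-01-03", cats = "manufacturer", count = 10),
    list(date = "2021-01-07", cats = "general_other", count = 30)
  )
  ws <- weekly_shares(make_classified(rows), "2021-01-01", "2021-01-07")
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$total_volume, 100)
  expect_equal(ws$availability, 0.60)
  expect_equal(ws$manufacturer, 0.10)
  expect_equal(ws$general_other, 0.30)
  expect_equal(ws$pharmacy, 0.60)

  # a doubly-labeled query counts fully in both categories
  both <- make_classified(list(
    list(date = "2021-01-01", cats = c("availability", "manufacturer"), count = 10)
  ))
  ws2 <- weekly_shares(both, "2021-01-01", "2021-01-07")
  expect_equal(ws2$availability, 1)
  expect_equal(ws2$manufacturer, 1)
  expect_equal(ws2$general_other, 0)
})

test_that("weeks are 7-day blocks from the window start; trailing days drop", {
  # 75-day window: 10 full weeks, 5 trailing days dropped
  start <- as.Date("2021-01-01")
  end <- as.Date("2021-03-16")
  expect_equal(as.integer(end - start) + 1L, 75L)
  rows <- lapply(0:74, function(d) {
    list(date = as.character(start + d), cats = "general_other", count = 1)
  })
  ws <- weekly_shares(make_classified(rows), start, end)
  expect_equal(nrow(ws), 10L)
  expect_equal(ws$week_index, 0:9)
  expect_equal(ws$week_start, start + 7 * (0:9))
  expect_equal(sum(ws$total_volume), 70) # 5 trailing days dropped
  # every retained record lands in exactly one week
  expect_equal(ws$total_volume, rep(7, 10))
})

test_that("degenerate weekly inputs raise errors", {
  rows <- list(list(date = "2021-01-01", cats = "general_other", count = 1))
  x <- make_classified(rows)
  expect_error(weekly_shares(x, "2021-01-05", "2021-01-01"), class = "vaxquery_config_error")
  # a retained week without volume
  expect_error(
    weekly_shares(x, "2021-01-01", "2021-01-14"),
    class = "vaxquery_degenerate_data"
  )
})

test_that("trend fit matches the hand-derived series and flags degeneracy", {
  perfect <- fit_trend(data.frame(week_index = 1:3, share = 1:3))
  expect_equal(perfect$beta, 1)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$df, 1L)

  fit <- fit_trend(data.frame(week_index = 1:5, share = c(2, 4, 5, 4, 5)))
  expect_equal(fit$beta, 0.6, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.6, tolerance = 1e-12)
  expect_equal(fit$df, 3L)

  flat <- fit_trend(data.frame(week_index = 1:5, share = rep(0.4, 5)))
  expect_true(flat$degenerate)
  expect_equal(flat$beta, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(
    fit_trend(data.frame(week_index = rep(1, 5), share = 1:5)),
    class = "vaxquery_invalid_fit"
  )
  expect_error(
    fit_trend(data.frame(week_index = 1:2, share = 1:2)),
    class = "vaxquery_invalid_fit"
  )
})

test_that("trend fit agrees with closed-form least squares on random series", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(5:50, 1))
    t <- seq_len(n)
    y <- withr::with_seed(seed * 7 + 1, rnorm(n, 0.5 + 0.02 * t, 0.1))
    fit <- fit_trend(data.frame(week_index = t, share = y))
    want <- ols_oracle(t, y)
    expect_equal(fit$beta, want$beta, tolerance = 1e-10)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-10)
    expect_equal(fit$df, want$df)
    expect_equal(fit$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("tidy and glance expose broom-style summaries", {
  fit <- fit_trend(data.frame(week_index = 1:5, share = c(2, 4, 5, 4, 5)))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "time"))
  expect_equal(td$estimate, c(2.2, 0.6), tolerance = 1e-12)
  gl <- glance(fit)
  expect_named(
    gl,
    c("beta", "intercept", "r_squared", "df", "p_value", "n_points", "degenerate")
  )
})

test_that("RSV normalization scales to a joint 0-100 peak", {
  d <- as.Date("2021-01-01") + 0:2
  one <- rsv_normalize(tibble::tibble(date = d, label = "a", count = c(5, 10, 20)))
  expect_equal(one$rsv, c(25, 50, 100))
  joint <- rsv_normalize(tibble::tibble(
    date = rep(d[1:2], 2), label = rep(c("a", "b"), each = 2),
    count = c(10, 20, 40, 80)
  ))
  expect_equal(joint$rsv, c(12.5, 25, 50, 100))
  constant <- rsv_normalize(tibble::tibble(date = d[1:2], label = "a", count = c(7, 7)))
  expect_equal(constant$rsv, c(100, 100))
  expect_error(
    rsv_normalize(tibble::tibble(date = d[1], label = "a", count = 0)),
    class = "vaxquery_degenerate_data"
  )
})

test_that("RSV is scale invariant and exactly the peak points reach 100", {
  for (seed in 1:50) {
    counts <- withr::with_seed(seed, sample(0:1000, 30, replace = TRUE))
    if (all(counts == 0)) counts[1] <- 1
    base <- tibble::tibble(
      date = rep(as.Date("2021-01-01") + 0:14, 2),
      label = rep(c("a", "b"), each = 15),
      count = counts
    )
    r1 <- rsv_normalize(base)
    c_mult <- withr::with_seed(seed + 99, runif(1, 0.1, 50))
    r2 <- rsv_normalize(dplyr::mutate(base, count = count * c_mult))
    expect_equal(r1$rsv, r2$rsv, tolerance = 1e-12)
    expect_equal(which(r1$rsv == 100), which(base$count == max(base$count)))
    expect_true(all(r1$rsv >= 0 & r1$rsv <= 100))
  }
})

test_that("per-label RSV normalizes each series against its own peak", {
  d <- as.Date("2021-01-01") + 0:1
  r <- rsv_normalize(
    tibble::tibble(
      date = rep(d, 2), label = rep(c("a", "b"), each = 2),
      count = c(10, 20, 40, 80)
    ),
    joint = FALSE
  )
  expect_equal(r$rsv, c(50, 100, 50, 100))
  ri <- rsv_normalize(
    tibble::tibble(date = d, label = "a", count = c(3, 9)),
    round = TRUE
  )
  expect_equal(ri$rsv, c(33, 100))
})

test_that("top-k volume share matches direct ratios and harmonic sums", {
  expect_equal(
    topk_volume_share(tibble::tibble(count = rep(2, 10)), 3), 3 / 10
  )
  expect_equal(
    topk_volume_share(tibble::tibble(count = c(50, 30, 20)), 1), 0.5
  )
  zipf_counts <- tibble::tibble(count = zipf_weights(1000, 1) * 1e6)
  expect_equal(
    topk_volume_share(zipf_counts, 150),
    harmonic(150) / harmonic(1000),
    tolerance = 1e-12
  )
  # monotone non-decreasing in k, equal to 1 at the universe size
  counts <- tibble::tibble(count = c(9, 5, 5, 2, 1))
  shares <- vapply(1:5, topk_volume_share, numeric(1), data = counts)
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[5], 1)
})

test_that("share ratio series is the pointwise fraction with guards", {
  d <- tibble::tibble(
    date = as.Date("2021-01-01") + 0:1, num = c(10, 50), den = c(100, 100)
  )
  expect_equal(share_ratio_series(d, num, den)$share, c(0.10, 0.50))
  expect_equal(share_ratio_series(d, den, den)$share, c(1, 1))
  expect_equal(
    share_ratio_series(dplyr::mutate(d, num = 0), num, den)$share, c(0, 0)
  )
  expect_error(
    share_ratio_series(dplyr::mutate(d, den = c(0, 100)), num, den),
    class = "vaxquery_degenerate_data"
  )
  expect_error(
    share_ratio_series(dplyr::mutate(d, num = 200), num, den),
    class = "vaxquery_config_error"
  )
})
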
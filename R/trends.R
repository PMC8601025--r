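#' Weekly volume-weighted category proportions
#'
#' Aggregates a classified query log into consecutive 7-day blocks anchored
#' at the study start date (a trailing partial block is dropped) and
#' computes, for each week, the volume-weighted share of each category:
#' `share(C, week)` is the summed count of queries carrying category `C`
#' divided by the total week volume. Because classification is multi-label,
#' the four specific-category shares can sum to more than their joint mass;
#' `general_other` is exclusive, so its share plus the share of queries with
#' at least one specific category is exactly 1. The pharmacy share is the
#' analogous ratio for pharmacy-flagged queries and never exceeds the
#' availability share.
#'
#' @param classified Output of [classify_queries()] (or a data frame with
#'   `date`, `count`, `categories`, `pharmacy`; `categories` may be a list
#'   column or a `;`-joined character column as read from disk).
#' @param start,end Study window (Date or ISO-8601 string); `start` anchors
#'   the weekly blocks and all record dates must fall inside the window.
#' @return A `weekly_shares` tibble with `week_index` (0-based),
#'   `week_start`, `total_volume`, one share column per category
#'   (fractions in `[0, 1]`) and `pharmacy`.
#' @export
weekly_shares <- function(classified, start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || end <= start) {
    abort("study window must satisfy start < end", class = "vaxquery_config_error")
  }
  n_weeks <- (as.integer(end - start) + 1L) %/% 7L
  if (n_weeks < 1L) {
    abort("study window shorter than one full week", class = "vaxquery_degenerate_data")
  }
  data <- tibble::as_tibble(classified)
  req <- c("date", "count", "categories", "pharmacy")
  if (!all(req %in% names(data))) {
    abort(paste0(
      "classified data must have columns: ", paste(req, collapse = ", ")
    ), class = "vaxquery_config_error")
  }
  data$date <- as.Date(data$date)
  if (any(data$date < start | data$date > end)) {
    abort("record dates outside the study window", class = "vaxquery_config_error")
  }
  data$categories <- as_category_list(data$categories)
  data$week_index <- as.integer(as.integer(data$date - start) %/% 7L)
  data <- dplyr::filter(data, .data$week_index < n_weeks) # drop trailing partial

  totals <- data |>
    dplyr::group_by(.data$week_index) |>
    dplyr::summarise(
      total_volume = sum(.data$count),
      pharmacy = sum(.data$count[.data$pharmacy]),
      .groups = "drop"
    )
  if (nrow(totals) < n_weeks || any(totals$total_volume <= 0)) {
    abort("every retained week needs positive query volume",
      class = "vaxquery_degenerate_data"
    )
  }

  long <- data |>
    dplyr::select("week_index", "count", "categories") |>
    tidyr::unnest_longer(dplyr::all_of("categories"), values_to = "category") |>
    dplyr::group_by(.data$week_index, .data$category) |>
    dplyr::summarise(volume = sum(.data$count), .groups = "drop")

  wide <- long |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "volume", values_fill = 0L
    )
  for (cc in setdiff(vax_categories, names(wide))) wide[[cc]] <- 0L

  out <- dplyr::left_join(totals, wide, by = "week_index") |>
    dplyr::arrange(.data$week_index)
  out[is.na(out)] <- 0
  for (cc in vax_categories) out[[cc]] <- out[[cc]] / out$total_volume
  out$pharmacy <- out$pharmacy / out$total_volume
  out <- out |>
    dplyr::mutate(week_start = start + .data$week_index * 7L) |>
    dplyr::select(
      "week_index", "week_start", "total_volume",
      dplyr::all_of(vax_categories), "pharmacy"
    )
  class(out) <- c("weekly_shares", class(out))
  out
}

#' Fit a linear time trend to a weekly proportion series
#'
#' Ordinary least squares of a proportion on week number, the trend model
#' used for every per-category time-trend reported by the package. Returns
#' slope (`beta`), intercept, coefficient of determination, residual degrees
#' of freedom (`n - 2`), and the two-sided t-test p-value for the slope.
#' A constant response is reported as a degenerate fit with `beta = 0` and
#' `r_squared = 0` rather than an error; a constant predictor is an error.
#'
#' @param data Data frame holding the series.
#' @param time,value Columns (tidy-eval) with the time index (e.g. week
#'   number) and the proportion. Defaults `week_index` / `share`.
#' @return A `trend_fit` object; see [tidy()] and [glance()] methods, and
#'   [fit_category_trends()] for the all-categories table.
#' @examples
#' fit <- fit_trend(data.frame(week_index = 1:5, share = c(2, 4, 5, 4, 5)))
#' glance(fit)
#' @export
fit_trend <- function(data, time = week_index, value = share) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  n <- length(t)
  if (n < 3L) {
    abort("trend fit needs at least 3 points", class = "vaxquery_invalid_fit")
  }
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    abort("trend fit needs finite inputs", class = "vaxquery_invalid_fit")
  }
  if (length(unique(t)) == 1L) {
    abort("constant time predictor: cannot fit a trend",
      class = "vaxquery_invalid_fit"
    )
  }
  degenerate <- length(unique(y)) == 1L
  if (degenerate) {
    res <- list(
      beta = 0, intercept = mean(y), r_squared = 0,
      df = n - 2L, p_value = NA_real_, n_points = n,
      degenerate = TRUE, model = NULL
    )
  } else {
    fit <- lm(y ~ t)
    # an exactly collinear series is a legitimate input (R^2 = 1), not a
    # numerical problem worth a user-facing warning
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    res <- list(
      beta = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      df = n - 2L,
      p_value = unname(sm$coefficients[2, 4]),
      n_points = n,
      degenerate = FALSE,
      model = fit
    )
  }
  res$data <- tibble::tibble(time = t, value = y)
  structure(res, class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> beta = %.4g, intercept = %.4g, R^2 = %.3f, df = %d, p = %s%s\n",
    x$beta, x$intercept, x$r_squared, x$df,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    if (x$degenerate) " (degenerate: constant response)" else ""
  ))
  invisible(x)
}

#' @rdname fit_trend
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(
      term = c("(Intercept)", "time"),
      estimate = c(x$intercept, 0),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  sm <- unname(summary(x$model)$coefficients)
  tibble::tibble(
    term = c("(Intercept)", "time"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname fit_trend
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, intercept = x$intercept, r_squared = x$r_squared,
    df = x$df, p_value = x$p_value, n_points = x$n_points,
    degenerate = x$degenerate
  )
}

#' Per-category linear time trends from weekly shares
#'
#' Fits [fit_trend()] to each category's weekly proportion series (plus the
#' pharmacy subcategory). By default shares are rescaled to percent before
#' fitting, so `beta` reads as percentage points per week.
#'
#' @param shares A [weekly_shares()] tibble.
#' @param scale `"percent"` (default) or `"fraction"`.
#' @return A tibble with one row per category: `category`, `beta`,
#'   `intercept`, `r_squared`, `df`, `p_value`, `n_points`, `degenerate`.
#' @export
fit_category_trends <- function(shares, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  mult <- if (scale == "percent") 100 else 1
  labels <- c(vax_categories, "pharmacy")
  purrr::map_dfr(labels, function(cc) {
    fit <- fit_trend(
      tibble::tibble(week_index = shares$week_index, share = shares[[cc]] * mult)
    )
    dplyr::bind_cols(tibble::tibble(category = cc), glance(fit))
  })
}

#' Relative search volume (RSV) normalization
#'
#' Rescales one or more daily count series to the 0-100 relative scale used
#' by public search-interest tools: every value is multiplied by
#' `100 / peak`, where the peak is taken across all series jointly (so
#' series remain comparable) or per series when `joint = FALSE`. After joint
#' normalization exactly the global-peak point(s) equal 100.
#'
#' @param data Data frame with columns `date`, `label`, `count`.
#' @param joint Normalize against the shared global maximum (default) rather
#'   than each series' own peak.
#' @param round Round to integers, mimicking public relative-search-volume
#'   output; off by default so values keep full precision.
#' @return An `rsv_series` tibble: `date`, `label`, `rsv`.
#' @examples
#' rsv_normalize(data.frame(
#'   date = as.Date("2021-01-01") + 0:2, label = "a", count = c(5, 10, 20)
#' ))
#' @export
rsv_normalize <- function(data, joint = TRUE, round = FALSE) {
  data <- tibble::as_tibble(data)
  req <- c("date", "label", "count")
  if (!all(req %in% names(data))) {
    abort("rsv input needs columns date, label, count",
      class = "vaxquery_config_error"
    )
  }
  if (any(data$count < 0)) {
    abort("counts must be non-negative", class = "vaxquery_config_error")
  }
  if (nrow(data) == 0 || all(data$count == 0)) {
    abort("all-zero counts cannot be normalized",
      class = "vaxquery_degenerate_data"
    )
  }
  out <- if (joint) {
    dplyr::mutate(data, rsv = .data$count * 100 / max(.data$count))
  } else {
    data |>
      dplyr::group_by(.data$label) |>
      dplyr::mutate(rsv = .data$count * 100 / max(.data$count)) |>
      dplyr::ungroup()
  }
  if (any(!is.finite(out$rsv))) {
    abort("a series with zero peak cannot be normalized per-series",
      class = "vaxquery_degenerate_data"
    )
  }
  if (round) out$rsv <- round(out$rsv)
  out <- dplyr::select(out, "date", "label", "rsv")
  class(out) <- c("rsv_series", class(out))
  out
}

#' Volume share of the top-k queries
#'
#' Fraction of total search volume contributed by the `k` highest-volume
#' queries — the concentration statistic behind heavy-tailed ("a few queries
#' carry most of the volume") rank-frequency summaries.
#'
#' @param data Data frame with a `count` column (one row per distinct
#'   query).
#' @param k Positive integer.
#' @return A fraction in `(0, 1]`.
#' @export
topk_volume_share <- function(data, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  counts <- tibble::as_tibble(data)$count
  if (is.null(counts) || !length(counts)) {
    abort("`data` must have a non-empty `count` column",
      class = "vaxquery_config_error"
    )
  }
  counts <- sort(counts, decreasing = TRUE)
  sum(counts[seq_len(min(k, length(counts)))]) / sum(counts)
}

#' Pointwise share of a sub-volume in a total volume
#'
#' Given matched daily series of a numerator count (e.g. vaccine-related
#' queries) and a denominator count (e.g. all COVID-19-related queries),
#' returns the pointwise fraction — the statistic used to track how the
#' vaccine-related share of all pandemic searches evolves.
#'
#' @param data Data frame holding both series.
#' @param numerator,denominator Columns (tidy-eval) with the counts;
#'   pointwise `0 <= numerator <= denominator` and `denominator > 0` are
#'   required.
#' @return The input tibble with an added `share` column in `[0, 1]`.
#' @export
share_ratio_series <- function(data, numerator, denominator) {
  data <- tibble::as_tibble(data)
  num <- dplyr::pull(data, {{ numerator }})
  den <- dplyr::pull(data, {{ denominator }})
  if (any(den <= 0)) {
    abort("denominator must be positive at every point",
      class = "vaxquery_degenerate_data"
    )
  }
  if (any(num < 0) || any(num > den)) {
    abort("numerator must satisfy 0 <= numerator <= denominator pointwise",
      class = "vaxquery_config_error"
    )
  }
  data$share <- num / den
  data
}
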
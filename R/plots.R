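#' Plot weekly category shares
#'
#' Line plot of the weekly volume-weighted share of each query category
#' (percent scale), the package's analogue of a category-trend panel.
#'
#' @param object A [weekly_shares()] tibble.
#' @param categories Which share columns to draw (default: all five
#'   categories plus pharmacy).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weekly_shares
#' @export
autoplot.weekly_shares <- function(object,
                                   categories = c(vax_categories, "pharmacy"),
                                   ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(categories),
      names_to = "category", values_to = "share"
    ) |>
    dplyr::mutate(category = factor(.data$category, levels = categories))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$week_start, y = 100 * .data$share, colour = .data$category
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "week", y = "share of weekly query volume (%)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.weekly_shares
#' @export
plot_weekly_shares <- function(object, categories = c(vax_categories, "pharmacy"), ...) {
  autoplot.weekly_shares(object, categories = categories, ...)
}

#' Plot a fitted linear time trend
#'
#' Scatter of the weekly proportions with the fitted OLS line.
#'
#' @param object A [fit_trend()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$beta, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "week", y = "proportion",
      subtitle = sprintf(
        "beta = %.3g, R² = %.2f, df = %d", object$beta,
        object$r_squared, object$df
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot relative search volume series
#'
#' Line plot of jointly normalized 0-100 relative-search-volume series.
#'
#' @param object An `rsv_series` tibble from [rsv_normalize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsv_series
#' @export
autoplot.rsv_series <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$date, y = .data$rsv, colour = .data$label)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "relative search volume (0-100)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rsv_series
#' @export
plot_rsv <- function(object, ...) {
  autoplot.rsv_series(object, ...)
}
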
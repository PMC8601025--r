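#' Read a raw query log
#'
#' Reads a TSV or CSV (by file extension) with header columns `date`
#' (ISO-8601), `query` (UTF-8 string) and optionally `count` (non-negative
#' integer; defaults to 1 when absent).
#'
#' @param path Path to the log file.
#' @return A tibble with `date`, `query`, `count`.
#' @export
read_query_log <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("query log not found: ", path), class = "vaxquery_config_error")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("date", "query") %in% names(data))) {
    abort("query log needs `date` and `query` columns",
      class = "vaxquery_config_error"
    )
  }
  data$date <- as.Date(data$date)
  if (!"count" %in% names(data)) data$count <- 1L
  if (any(is.na(data$count)) || any(data$count < 0)) {
    abort("`count` must be non-negative", class = "vaxquery_config_error")
  }
  tibble::as_tibble(data[c("date", "query", "count")])
}

#' Write / read classified queries as TSV
#'
#' On-disk form: `date`, `query`, `count`, `categories` (semicolon-joined in
#' the fixed [vax_categories] order), `pharmacy` (0/1) and `matched_terms`
#' (`pattern|category` pairs, semicolon-joined). [read_classified()] inverts
#' the encoding, restoring the list columns.
#'
#' @param classified Output of [classify_queries()].
#' @param path Destination TSV path.
#' @return `path`, invisibly (writer); a classified tibble (reader).
#' @export
write_classified <- function(classified, path) {
  out <- tibble::as_tibble(classified)
  out$categories <- vapply(
    as_category_list(out$categories),
    paste, character(1), collapse = ";"
  )
  out$pharmacy <- as.integer(out$pharmacy)
  if ("matched_terms" %in% names(out)) {
    out$matched_terms <- vapply(out$matched_terms, function(m) {
      if (is.null(m) || !nrow(m)) "" else paste(m$pattern, m$category, sep = "|", collapse = ";")
    }, character(1))
  } else {
    out$matched_terms <- ""
  }
  readr::write_tsv(
    out[c("date", "query", "count", "categories", "pharmacy", "matched_terms")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_classified
#' @export
read_classified <- function(path) {
  data <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      date = readr::col_date(), query = readr::col_character(),
      count = readr::col_integer(), categories = readr::col_character(),
      pharmacy = readr::col_integer(), matched_terms = readr::col_character()
    )
  )
  data$categories <- as_category_list(data$categories)
  data$pharmacy <- data$pharmacy == 1L
  data$matched_terms <- lapply(data$matched_terms, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(pattern = character(), category = character()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
    tibble::tibble(
      pattern = vapply(parts, `[`, character(1), 1),
      category = vapply(parts, `[`, character(1), 2)
    )
  })
  data
}

#' Write / read gold labels as TSV
#'
#' Columns: `date`, `query`, `categories` (semicolon-joined), `pharmacy`
#' (0/1).
#'
#' @param gold Gold-label tibble (e.g. from [generate_log()]).
#' @param path TSV path.
#' @return `path` invisibly (writer); a gold tibble (reader).
#' @export
write_gold <- function(gold, path) {
  out <- tibble::as_tibble(gold)
  out$categories <- vapply(
    as_category_list(out$categories),
    paste, character(1), collapse = ";"
  )
  out$pharmacy <- as.integer(out$pharmacy)
  readr::write_tsv(out[c("date", "query", "categories", "pharmacy")], path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  data <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      date = readr::col_date(), query = readr::col_character(),
      categories = readr::col_character(), pharmacy = readr::col_integer()
    )
  )
  data$categories <- as_category_list(data$categories)
  data$pharmacy <- data$pharmacy == 1L
  data
}

#' Write weekly shares / trend results / evaluation report
#'
#' `write_weekly_shares()` writes the [weekly_shares()] table as CSV at full
#' float precision. `write_trend_results()` writes the
#' [fit_category_trends()] table as a JSON object keyed by category.
#' `write_eval_report()` writes a [precision_recall()] report (plus optional
#' coverage) as JSON.
#'
#' @param shares,trends,report The respective result objects.
#' @param path Destination path.
#' @param coverage Optional coverage fraction stored alongside the report.
#' @return `path`, invisibly.
#' @export
write_weekly_shares <- function(shares, path) {
  readr::write_csv(tibble::as_tibble(shares), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_weekly_shares
#' @export
read_weekly_shares <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("weekly_shares", class(out))
  out
}

#' @rdname write_weekly_shares
#' @export
write_trend_results <- function(trends, path) {
  obj <- split(
    trends[setdiff(names(trends), "category")],
    factor(trends$category, levels = trends$category)
  )
  obj <- lapply(obj, function(row) as.list(row))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_weekly_shares
#' @export
read_trend_results <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::imap_dfr(obj, function(row, cat) {
    tibble::as_tibble(lapply(row, function(v) v %||% NA_real_)) |>
      dplyr::mutate(category = cat, .before = 1)
  })
}

#' @rdname write_weekly_shares
#' @export
write_eval_report <- function(report, path, coverage = NULL) {
  obj <- list(
    n_queries = attr(report, "n_queries"),
    labels = lapply(split(
      tibble::as_tibble(report),
      factor(report$label, levels = report$label)
    ), as.list)
  )
  if (!is.null(coverage)) obj$specific_coverage <- coverage
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write / read RSV series as CSV
#'
#' Columns `date`, `label`, `rsv` at full precision.
#'
#' @param rsv An `rsv_series` tibble from [rsv_normalize()].
#' @param path CSV path.
#' @return `path` invisibly (writer); an `rsv_series` tibble (reader).
#' @export
write_rsv <- function(rsv, path) {
  readr::write_csv(tibble::as_tibble(rsv), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rsv
#' @export
read_rsv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("rsv_series", class(out))
  out
}
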
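#' Does a token sequence belong to the study universe?
#'
#' The study inclusion rule keeps a query only when it contains both a
#' covid-equivalent and a vaccine-equivalent term (after spelling-variant
#' resolution), mirroring the query-log sampling filter that defines a
#' COVID-19 vaccine-related search.
#'
#' @param tokens Character vector of normalized tokens ([normalize_text()]).
#' @param lexicon A `vax_lexicon`.
#' @return Logical scalar.
#' @examples
#' lex <- default_lexicon()
#' is_study_query(normalize_text("covid vaccine near me"), lex)
#' is_study_query(normalize_text("flu shot"), lex)
#' @export
is_study_query <- function(tokens, lexicon) {
  lexicon <- as_vax_lexicon(lexicon)
  tokens <- resolve_variant(tokens, lexicon)
  any(tokens %in% lexicon$filter_terms$covid) &&
    any(tokens %in% lexicon$filter_terms$vaccine)
}

#' Keep only queries passing the covid+vaccine inclusion filter
#'
#' Data-frame interface to [is_study_query()]: rows whose query text lacks
#' either a covid-equivalent or a vaccine-equivalent term are dropped.
#'
#' @param data A data frame with at least a `query` column.
#' @param lexicon A `vax_lexicon` (default: the shipped lexicon).
#' @param fuzzy Apply optional edit-distance-1 token canonicalization before
#'   filtering (off by default; the curated variant table is always applied).
#' @return The filtered tibble.
#' @export
filter_study_queries <- function(data, lexicon = default_lexicon(), fuzzy = FALSE) {
  lexicon <- as_vax_lexicon(lexicon)
  data <- tibble::as_tibble(data)
  uq <- unique(data$query)
  padded <- canonical_padded(uq, lexicon, fuzzy = fuzzy)
  covid_pad <- pad_pattern(lexicon$filter_terms$covid)
  vax_pad <- pad_pattern(lexicon$filter_terms$vaccine)
  has_any <- function(pads) {
    Reduce(`|`, lapply(pads, function(p) {
      stringr::str_detect(padded, stringr::fixed(p))
    }))
  }
  keep_uq <- has_any(covid_pad) & has_any(vax_pad)
  dplyr::filter(data, .data$query %in% uq[keep_uq])
}

#' Classify queries into vaccine-search categories
#'
#' The rules-based multi-label classifier. Each query is normalized
#' ([normalize_text()]), spelling variants are canonicalized, and every
#' lexicon pattern is matched as a contiguous token subsequence. The query
#' receives every specific category (availability, manufacturer,
#' side-effects/safety, myths/conspiracy) with at least one firing pattern;
#' queries matching none fall back to the exclusive `general_other` category,
#' so every query is assigned at least one label. A query is flagged
#' `pharmacy` when any matched availability pattern is a pharmacy name
#' (pharmacy-flagged queries are always availability queries).
#'
#' Classification does not itself apply the covid+vaccine inclusion filter;
#' run [filter_study_queries()] first to restrict to the study universe.
#'
#' @param data A data frame with columns `query` (character), optionally
#'   `date` (Date) and `count` (non-negative integer volume, default 1).
#' @param lexicon A `vax_lexicon`.
#' @param fuzzy Enable edit-distance-1 token canonicalization on top of the
#'   curated variant table. Off by default: conservative exact matching is
#'   what keeps precision high.
#' @return A tibble with the input columns plus `categories` (list column of
#'   character vectors, in the fixed [vax_categories] order), `pharmacy`
#'   (logical) and `matched_terms` (list column of tibbles with `pattern`
#'   and `category` for every firing pattern, for audit).
#' @examples
#' lex <- default_lexicon()
#' classify_queries(
#'   tibble::tibble(query = c("pfizer covid vaccine cvs", "covid vaccine")),
#'   lex
#' )
#' @export
classify_queries <- function(data, lexicon = default_lexicon(), fuzzy = FALSE) {
  lexicon <- as_vax_lexicon(lexicon)
  data <- tibble::as_tibble(data)
  if (!"query" %in% names(data)) {
    abort("`data` must have a `query` column", class = "vaxquery_config_error")
  }
  if (!"count" %in% names(data)) data$count <- 1L
  if (any(data$count < 0)) {
    abort("`count` must be non-negative", class = "vaxquery_config_error")
  }

  uq <- unique(data$query)
  padded <- canonical_padded(uq, lexicon, fuzzy = fuzzy)
  if (any(padded == "")) {
    bad <- uq[padded == ""][1]
    abort(
      paste0("query normalizes to an empty token sequence: ", encodeString(bad)),
      class = "vaxquery_degenerate_input"
    )
  }

  pt <- lexicon$pattern_tbl
  fired <- vapply(
    pt$padded,
    function(p) stringr::str_detect(padded, stringr::fixed(p)),
    logical(length(padded)),
    USE.NAMES = FALSE
  )
  fired <- matrix(fired, nrow = length(padded)) # queries x patterns

  cats_per_query <- lapply(seq_along(padded), function(i) {
    hit <- unique(pt$category[fired[i, ]])
    if (!length(hit)) {
      "general_other"
    } else {
      vax_categories[vax_categories %in% hit]
    }
  })
  pharmacy <- as.logical(fired %*% pt$pharmacy > 0)
  matched <- lapply(seq_along(padded), function(i) {
    tibble::tibble(pattern = pt$pattern[fired[i, ]], category = pt$category[fired[i, ]])
  })

  idx <- match(data$query, uq)
  out <- data
  out$categories <- cats_per_query[idx]
  out$pharmacy <- pharmacy[idx]
  out$matched_terms <- matched[idx]
  class(out) <- c("classified_queries", class(out))
  out
}

#' Keep the top-k queries per day by volume
#'
#' Emulates per-day truncated query-log sampling: for every calendar date
#' only the `k` highest-volume records are retained. Ties on count are
#' broken deterministically by lexicographic query text (ascending).
#'
#' @param data A data frame with `date`, `query` and `count` columns.
#' @param k Positive integer, records retained per day.
#' @return The truncated tibble, ordered by date, then descending count,
#'   then query text.
#' @export
daily_topk <- function(data, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  data <- tibble::as_tibble(data)
  data |>
    dplyr::arrange(.data$date, dplyr::desc(.data$count), .data$query) |>
    dplyr::group_by(.data$date) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::ungroup()
}

# accept either a list-column of category vectors or a ";"-joined character
# column (the on-disk form) and return a list-column
as_category_list <- function(categories) {
  if (is.list(categories)) return(categories)
  strsplit(as.character(categories), ";", fixed = TRUE)
}
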
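#' Per-category precision and recall against gold labels
#'
#' Scores multi-label classifier output one-vs-rest: for every category a
#' query is a true positive when the category appears in both the predicted
#' and gold sets, a false positive when predicted only, and a false negative
#' when gold only. The pharmacy flag is scored as its own binary label.
#' Precision is `TP / (TP + FP)` and recall `TP / (TP + FN)`; a `0/0` ratio
#' is reported as `NA` with the matching `*_defined` flag set to `FALSE`
#' rather than silently mapped to 0 or 1. Counting is per query record
#' (unweighted by volume).
#'
#' Predicted and gold must cover the same query multiset; records are joined
#' on `(date, query)` and any orphan on either side is an error.
#'
#' @param predicted Output of [classify_queries()] (needs `date`, `query`,
#'   `categories`, `pharmacy`).
#' @param gold Gold labels: `date`, `query`, `categories` (list column or
#'   `;`-joined character) and `pharmacy` (logical or 0/1).
#' @return An `eval_report` tibble with one row per label (`label`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `precision_defined`,
#'   `recall_defined`); the number of scored queries is in the `n_queries`
#'   attribute.
#' @export
precision_recall <- function(predicted, gold) {
  p <- prep_labels(predicted, "predicted")
  g <- prep_labels(gold, "gold")

  orphans_p <- dplyr::anti_join(p, g, by = c("date", "query"))
  orphans_g <- dplyr::anti_join(g, p, by = c("date", "query"))
  if (nrow(orphans_p) || nrow(orphans_g)) {
    ex <- utils::head(unique(c(orphans_p$query, orphans_g$query)), 5)
    abort(
      paste0(
        "predicted and gold must cover the same (date, query) multiset; ",
        nrow(orphans_p), " predicted-only and ", nrow(orphans_g),
        " gold-only records, e.g.: ", paste(encodeString(ex), collapse = ", ")
      ),
      class = "vaxquery_join_error"
    )
  }

  joined <- dplyr::inner_join(p, g,
    by = c("date", "query"), suffix = c("_pred", "_gold")
  )
  labels <- c(vax_categories, "pharmacy")
  rows <- purrr::map_dfr(labels, function(lab) {
    if (lab == "pharmacy") {
      pred_pos <- joined$pharmacy_pred
      gold_pos <- joined$pharmacy_gold
    } else {
      pred_pos <- purrr::map_lgl(joined$categories_pred, ~ lab %in% .x)
      gold_pos <- purrr::map_lgl(joined$categories_gold, ~ lab %in% .x)
    }
    tp <- sum(pred_pos & gold_pos)
    fp <- sum(pred_pos & !gold_pos)
    fn <- sum(!pred_pos & gold_pos)
    tibble::tibble(
      label = lab, tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision_defined = tp + fp > 0,
      recall_defined = tp + fn > 0
    )
  })
  attr(rows, "n_queries") <- nrow(joined)
  class(rows) <- c("eval_report", class(rows))
  rows
}

prep_labels <- function(data, what) {
  data <- tibble::as_tibble(data)
  req <- c("date", "query", "categories", "pharmacy")
  if (!all(req %in% names(data))) {
    abort(
      paste0(what, " data must have columns: ", paste(req, collapse = ", ")),
      class = "vaxquery_config_error"
    )
  }
  data$categories <- as_category_list(data$categories)
  data$pharmacy <- as.logical(data$pharmacy)
  if (anyDuplicated(data[c("date", "query")])) {
    abort(paste0(what, " data has duplicate (date, query) records"),
      class = "vaxquery_join_error"
    )
  }
  data[req]
}

#' Fraction of query volume matched by an explicit pattern
#'
#' The coverage statistic: the (by default volume-weighted) fraction of
#' queries whose category set contains a specific category, or whose full
#' normalized text equals one of the explicit bare "general" query forms
#' (e.g. `"covid vaccine"`). The complement is the residual "other" mass —
#' queries the lexicon says nothing about beyond the fallback.
#'
#' @param predicted Output of [classify_queries()].
#' @param lexicon A `vax_lexicon`; supplies the default `general_patterns`
#'   and the variant table used to normalize query text.
#' @param general_patterns Character vector of whole-query general forms
#'   (default: the lexicon's `general_patterns`).
#' @param weighted Weight queries by their `count` (default) rather than
#'   counting each record once.
#' @return A fraction in `[0, 1]`.
#' @export
specific_coverage <- function(predicted, lexicon = default_lexicon(),
                              general_patterns = NULL, weighted = TRUE) {
  lexicon <- as_vax_lexicon(lexicon)
  if (is.null(general_patterns)) general_patterns <- lexicon$general_patterns
  data <- tibble::as_tibble(predicted)
  if (!nrow(data)) {
    abort("predicted data must be non-empty", class = "vaxquery_degenerate_data")
  }
  data$categories <- as_category_list(data$categories)
  if (!"count" %in% names(data)) data$count <- 1L
  w <- if (weighted) data$count else rep(1L, nrow(data))

  specific <- purrr::map_lgl(
    data$categories,
    ~ any(.x %in% specific_categories())
  )
  padded <- canonical_padded(data$query, lexicon)
  general_padded <- pad_pattern(general_patterns)
  general_hit <- padded %in% general_padded # whole-query equality
  sum(w[specific | general_hit]) / sum(w)
}
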
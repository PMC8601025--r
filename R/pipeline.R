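#' Run the full analysis pipeline
#'
#' One reproducible end-to-end run: obtain a query log (either a provided
#' log or a synthetic one generated from `config`), apply the covid+vaccine
#' inclusion filter and optional per-day top-k truncation, classify every
#' query, aggregate weekly volume-weighted category shares, fit per-category
#' linear time trends, optionally score against gold labels, and write all
#' artifacts plus a machine-readable run manifest (input checksums, config
#' echo, package and lexicon versions) under `out_dir`.
#'
#' Artifacts written: `classified.tsv`, `weekly_shares.csv`,
#' `trend_results.json`, `evaluation.json` (when gold labels are available),
#' `generated_log.tsv` + `gold.tsv` (when generating), `manifest.json`.
#'
#' @param log A query-log tibble (`date`, `query`, `count`), a path readable
#'   by [read_query_log()], or `NULL` to generate from `config`.
#' @param config A [synthetic_config()] used when `log` is `NULL`.
#' @param lexicon A `vax_lexicon` or path to a lexicon JSON.
#' @param gold Gold labels (tibble or TSV path); defaults to the generator's
#'   gold labels when generating.
#' @param window Length-2 study window (start, end). Defaults to the span of
#'   the log.
#' @param out_dir Output directory, created if needed.
#' @param apply_filter Apply [filter_study_queries()] before classification
#'   (default TRUE).
#' @param topk Optional per-day truncation before classification.
#' @param fuzzy Enable edit-distance-1 canonicalization in classification.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `classified`, `shares`, `trends`,
#'   `evaluation` (or `NULL`), `coverage`, and `manifest`.
#' @export
run_pipeline <- function(log = NULL, config = NULL,
                         lexicon = default_lexicon(), gold = NULL,
                         window = NULL, out_dir,
                         apply_filter = TRUE, topk = NULL, fuzzy = FALSE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  lexicon <- as_vax_lexicon(lexicon)
  if (is.null(log) && is.null(config)) {
    abort("provide either `log` or a synthetic `config`",
      class = "vaxquery_config_error"
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)

  if (is.null(log)) {
    stopifnot(inherits(config, "synthetic_config"))
    syn <- generate_log(config)
    log <- syn$records
    if (is.null(gold)) gold <- syn$gold
    p1 <- file.path(out_dir, "generated_log.tsv")
    readr::write_tsv(log, p1, progress = FALSE)
    p2 <- write_gold(syn$gold, file.path(out_dir, "gold.tsv"))
    artifacts <- c(artifacts, p1, p2)
    say("generate: %d records, %s total volume", nrow(log), format(sum(log$count), big.mark = ","))
  } else if (is.character(log)) {
    log <- read_query_log(log)
  } else {
    log <- tibble::as_tibble(log)
  }
  if (is.character(gold)) gold <- read_gold(gold)

  if (apply_filter) {
    n0 <- nrow(log)
    log <- filter_study_queries(log, lexicon)
    say("filter: kept %d of %d records", nrow(log), n0)
  }
  if (!is.null(topk)) {
    log <- daily_topk(log, topk)
    say("topk: %d records after per-day top-%d truncation", nrow(log), topk)
  }

  classified <- classify_queries(log, lexicon, fuzzy = fuzzy)
  artifacts <- c(artifacts, write_classified(classified, file.path(out_dir, "classified.tsv")))
  say("classify: %d records", nrow(classified))

  if (is.null(window)) window <- range(classified$date)
  shares <- weekly_shares(classified, window[1], window[2])
  artifacts <- c(artifacts, write_weekly_shares(shares, file.path(out_dir, "weekly_shares.csv")))
  say("weekly_shares: %d weeks", nrow(shares))

  trends <- fit_category_trends(shares)
  artifacts <- c(artifacts, write_trend_results(trends, file.path(out_dir, "trend_results.json")))

  evaluation <- NULL
  coverage <- specific_coverage(classified, lexicon)
  if (!is.null(gold)) {
    gold <- dplyr::semi_join(
      tibble::as_tibble(gold), classified,
      by = c("date", "query")
    )
    evaluation <- precision_recall(classified, gold)
    artifacts <- c(artifacts, write_eval_report(
      evaluation, file.path(out_dir, "evaluation.json"),
      coverage = coverage
    ))
    say("evaluate: %d queries scored", attr(evaluation, "n_queries"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vaxquery")),
    lexicon_version = lexicon$version,
    window = as.character(as.Date(window)),
    apply_filter = apply_filter,
    topk = topk,
    fuzzy = fuzzy,
    config = if (!is.null(config)) unclass_config(config) else NULL,
    artifacts = setNames(
      as.list(unname(tools::md5sum(artifacts))),
      basename(artifacts)
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  say("manifest: %s", manifest_path)

  invisible(list(
    classified = classified, shares = shares, trends = trends,
    evaluation = evaluation, coverage = coverage, manifest = manifest
  ))
}

# config echo with JSON-friendly types
unclass_config <- function(config) {
  out <- unclass(config)
  out$start_date <- as.character(out$start_date)
  out$universe <- as.list(out$universe)
  out
}
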
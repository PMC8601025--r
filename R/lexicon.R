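#' Read a category lexicon from JSON
#'
#' A lexicon drives every matching step: the covid/vaccine inclusion filter,
#' the four specific category pattern lists, the pharmacy-name sublist of the
#' availability patterns, a curated spelling-variant table, and the list of
#' bare "general" query forms used by coverage scoring. The JSON layout is:
#'
#' ```json
#' {
#'   "version": "1.0.0",
#'   "filter_terms": {"covid": [...], "vaccine": [...]},
#'   "categories": {"availability": [...], "manufacturer": [...],
#'                  "side_effects_safety": [...], "myths_conspiracy": [...]},
#'   "pharmacy_names": [...],
#'   "variants": {"variant": "canonical", ...},
#'   "general_patterns": [...]
#' }
#' ```
#'
#' All patterns must be lower-case and non-empty; multi-token patterns match
#' as contiguous token subsequences after [normalize_text()] and variant
#' resolution. Pharmacy names must be a subset of the availability patterns.
#'
#' @param path Path to a lexicon JSON file.
#' @return A `vax_lexicon` object.
#' @seealso [default_lexicon()], [vax_lexicon()]
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path), class = "vaxquery_config_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vax_lexicon(
    categories = raw$categories,
    pharmacy_names = raw$pharmacy_names,
    filter_terms = raw$filter_terms,
    variants = unlist(raw$variants) %||% character(0),
    general_patterns = raw$general_patterns %||% character(0),
    version = raw$version %||% "unversioned"
  )
}

#' The lexicon shipped with the package
#'
#' A frozen, versioned reconstruction of the study vocabulary: all 50 US
#' state names plus common abbreviations, availability phrases ("near me",
#' "appointment", "where", "when", ...), a pharmacy-chain list (cvs,
#' walgreens, rite aid, walmart, ...), COVID-19 vaccine manufacturer names,
#' side-effect/safety terms, the five recurring myth/conspiracy themes
#' (infertility, DNA, microchip, 5G, catching COVID from the vaccine), and a
#' curated spelling-variant table. Users can extend it by editing a copy of
#' the JSON file (`system.file("extdata", "vaccine_lexicon.json", package =
#' "vaxquery")`) and loading it with [read_lexicon()].
#'
#' @return A `vax_lexicon` object.
#' @examples
#' lex <- default_lexicon()
#' lex
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "vaccine_lexicon.json",
    package = "vaxquery", mustWork = TRUE
  ))
}

#' Construct a lexicon from R objects
#'
#' Mostly useful for tests and programmatic lexicon construction; validates
#' the same invariants as [read_lexicon()].
#'
#' @param categories Named list with character pattern vectors for
#'   `availability`, `manufacturer`, `side_effects_safety`,
#'   `myths_conspiracy`.
#' @param pharmacy_names Character vector, subset of the availability
#'   patterns.
#' @param filter_terms Named list with elements `covid` and `vaccine`
#'   (inclusion-filter equivalents).
#' @param variants Named character vector mapping each spelling variant to
#'   exactly one canonical term.
#' @param general_patterns Character vector of bare general query forms
#'   (whole-query matches) used by [specific_coverage()].
#' @param version Version string carried into run manifests.
#' @return A `vax_lexicon` object.
#' @export
vax_lexicon <- function(categories, pharmacy_names = character(0),
                        filter_terms = list(covid = "covid", vaccine = "vaccine"),
                        variants = character(0),
                        general_patterns = character(0),
                        version = "adhoc") {
  need <- specific_categories()
  if (!all(need %in% names(categories))) {
    abort(
      paste0(
        "lexicon must define patterns for all of: ",
        paste(need, collapse = ", ")
      ),
      class = "vaxquery_config_error"
    )
  }
  categories <- lapply(categories[need], as.character)
  pharmacy_names <- as.character(pharmacy_names)
  variants <- unlist(variants) %||% character(0)
  all_pat <- c(
    unlist(categories, use.names = FALSE), pharmacy_names,
    unlist(filter_terms, use.names = FALSE), general_patterns
  )
  if (any(!nzchar(all_pat))) {
    abort("lexicon patterns must be non-empty strings",
      class = "vaxquery_config_error"
    )
  }
  if (any(all_pat != stringr::str_to_lower(all_pat))) {
    abort("lexicon patterns must be lower-case",
      class = "vaxquery_config_error"
    )
  }
  if (!all(pharmacy_names %in% categories$availability)) {
    abort("pharmacy_names must be a subset of the availability patterns",
      class = "vaxquery_config_error"
    )
  }
  if (length(variants) && anyDuplicated(names(variants))) {
    abort("each spelling variant must map to exactly one canonical term",
      class = "vaxquery_config_error"
    )
  }
  lex <- structure(
    list(
      version = version,
      filter_terms = lapply(filter_terms, as.character),
      categories = categories,
      pharmacy_names = pharmacy_names,
      variants = variants,
      general_patterns = as.character(general_patterns)
    ),
    class = "vax_lexicon"
  )
  # precompute padded canonical pattern strings for fast fixed-string search
  lex$pattern_tbl <- lexicon_pattern_table(lex)
  lex
}

as_vax_lexicon <- function(x) {
  if (inherits(x, "vax_lexicon")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_lexicon(x))
  abort("expected a vax_lexicon object or a path to a lexicon JSON file",
    class = "vaxquery_config_error"
  )
}

# one row per (pattern, category) with the padded normalized form used for
# contiguous-subsequence matching; pharmacy names flagged
lexicon_pattern_table <- function(lex) {
  tbl <- purrr::imap(lex$categories, function(patterns, cat) {
    tibble::tibble(pattern = patterns, category = cat)
  })
  tbl <- dplyr::bind_rows(tbl)
  tbl$padded <- pad_pattern(tbl$pattern)
  tbl$pharmacy <- tbl$category == "availability" &
    tbl$pattern %in% lex$pharmacy_names
  tbl
}

pad_pattern <- function(patterns) {
  vapply(patterns, function(p) {
    toks <- normalize_text(p)
    paste0(" ", paste(toks, collapse = " "), " ")
  }, character(1), USE.NAMES = FALSE)
}

# every token appearing in any pattern, filter term or variant canonical
lexicon_vocabulary <- function(lex) {
  pats <- c(
    unlist(lex$categories, use.names = FALSE),
    unlist(lex$filter_terms, use.names = FALSE),
    unname(lex$variants),
    lex$general_patterns
  )
  unique(unlist(lapply(pats, normalize_text), use.names = FALSE))
}

#' @export
print.vax_lexicon <- function(x, ...) {
  cat("<vax_lexicon> version", x$version, "\n")
  for (cat_name in names(x$categories)) {
    cat(sprintf("  %-20s %d patterns\n", cat_name, length(x$categories[[cat_name]])))
  }
  cat(sprintf(
    "  pharmacy names: %d | variants: %d | general patterns: %d\n",
    length(x$pharmacy_names), length(x$variants), length(x$general_patterns)
  ))
  invisible(x)
}
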
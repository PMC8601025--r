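#' Normalize query text into a token sequence
#'
#' Lower-cases a raw query, replaces punctuation (including hyphens and
#' ampersands, but not intra-word apostrophes) by spaces, splits digit
#' suffixes off "covid" (so `"covid19"` and `"covid-19"` both yield the
#' tokens `covid`, `19`), and splits on whitespace. This is the
#' normalization every matching operation in the package applies before
#' lexicon lookup, so matching is case- and punctuation-insensitive.
#'
#' @param raw A single query string (may be empty).
#' @return A character vector of tokens; `character(0)` for input with no
#'   alphanumeric content.
#' @examples
#' normalize_text("Pfizer COVID Vaccine CVS")
#' normalize_text("covid-19 vaccine")
#' @export
normalize_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- normalize_string(raw)
  if (!nzchar(s)) return(character(0))
  strsplit(s, " ", fixed = TRUE)[[1]]
}

# Vectorized core: normalized, space-collapsed string per input query.
normalize_string <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "covid(?=[0-9])", "covid ")
  x <- stringr::str_replace_all(x, "[^a-z0-9']+", " ")
  # apostrophes survive only between alphanumerics ("sam's"), else stripped
  x <- stringr::str_replace_all(x, "(?<![a-z0-9])'|'(?![a-z0-9])", " ")
  stringr::str_squish(x)
}

#' Resolve a spelling variant to its canonical term
#'
#' Looks a normalized token up in the lexicon's curated variant table and
#' returns the canonical term; tokens absent from the table are returned
#' unchanged. Resolution is applied to query tokens before any pattern or
#' filter matching. Only explicit table entries are resolved; no fuzzy
#' matching happens here (see the `fuzzy` argument of [classify_queries()]).
#'
#' @param token Character vector of normalized tokens.
#' @param lexicon A `vax_lexicon` object (see [read_lexicon()]).
#' @return Character vector of the same length with variants canonicalized.
#' @examples
#' lex <- default_lexicon()
#' resolve_variant(c("vaccinations", "johnson", "phizer"), lex)
#' @export
resolve_variant <- function(token, lexicon) {
  lexicon <- as_vax_lexicon(lexicon)
  hit <- match(token, names(lexicon$variants))
  out <- token
  out[!is.na(hit)] <- unname(lexicon$variants[hit[!is.na(hit)]])
  out
}

# normalize + variant-resolve a character vector of raw queries into
# space-padded canonical strings (" tok1 tok2 "), for contiguous
# token-subsequence matching via fixed string search. Empty queries map to "".
canonical_padded <- function(queries, lexicon, fuzzy = FALSE) {
  norm <- normalize_string(queries)
  toks <- strsplit(norm, " ", fixed = TRUE)
  toks <- lapply(toks, function(tt) {
    tt <- tt[nzchar(tt)]
    tt <- resolve_variant(tt, lexicon)
    if (fuzzy) tt <- resolve_variant(fuzzy_resolve(tt, lexicon), lexicon)
    tt
  })
  vapply(
    toks,
    function(tt) if (length(tt)) paste0(" ", paste(tt, collapse = " "), " ") else "",
    character(1)
  )
}

# Optional edit-distance-1 canonicalization (off by default): a token that is
# not already in the lexicon vocabulary is replaced by the unique vocabulary
# token at Levenshtein distance 1, when exactly one such token exists.
fuzzy_resolve <- function(tokens, lexicon) {
  if (!length(tokens)) return(tokens)
  vocab <- lexicon_vocabulary(lexicon)
  unknown <- unique(tokens[!(tokens %in% vocab)])
  if (!length(unknown)) return(tokens)
  d <- adist(unknown, vocab)
  repl <- vapply(seq_along(unknown), function(i) {
    hits <- which(d[i, ] == 1L)
    if (length(hits) == 1L) vocab[hits] else unknown[i]
  }, character(1))
  map <- setNames(repl, unknown)
  hit <- match(tokens, names(map))
  tokens[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  tokens
}
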
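# Template grammar vocabulary. Mirrors the shipped lexicon so generated
# queries are always lexicon-covered (gold category == grammar category);
# the gold-consistency test enforces this.
gen_states <- c(
  "alabama", "alaska", "arizona", "arkansas", "california", "colorado",
  "connecticut", "delaware", "florida", "georgia", "hawaii", "idaho",
  "illinois", "indiana", "iowa", "kansas", "kentucky", "louisiana", "maine",
  "maryland", "massachusetts", "michigan", "minnesota", "mississippi",
  "missouri", "montana", "nebraska", "nevada", "new hampshire",
  "new jersey", "new mexico", "new york", "north carolina", "north dakota",
  "ohio", "oklahoma", "oregon", "pennsylvania", "rhode island",
  "south carolina", "south dakota", "tennessee", "texas", "utah", "vermont",
  "virginia", "washington", "west virginia", "wisconsin", "wyoming"
)
gen_pharmacies <- c(
  "cvs", "walgreens", "rite aid", "walmart", "kroger", "costco", "safeway",
  "publix", "meijer", "sam's club"
)
gen_manufacturers <- c(
  "pfizer", "moderna", "johnson", "j&j", "janssen", "astrazeneca",
  "biontech", "novavax"
)
gen_se_terms <- c(
  "side effects", "safety", "reaction", "fever", "allergy", "blood clot",
  "headache", "sore arm", "chills", "fatigue", "nausea", "rash", "pregnant",
  "myocarditis"
)

# ordered candidate strings per slot; the head of each list is the Zipf head
gen_candidates <- function() {
  availability <- c(
    "covid vaccine near me", "where to get covid vaccine",
    "covid vaccine appointment", "when can i get covid vaccine",
    "covid vaccine appointment near me", "covid vaccine sign up",
    "covid vaccine registration", "covid vaccine finder",
    "covid vaccine clinic near me", "ny covid vaccine", "nyc covid vaccine",
    "covid vaccine nj", "covid vaccine tx", "covid vaccine fl",
    "covid vaccine pa",
    paste("covid vaccine", gen_states),
    paste(gen_states, "covid vaccine"),
    paste("covid vaccine appointment", gen_states),
    paste("where to get covid vaccine in", gen_states),
    paste("when can i get covid vaccine in", gen_states)
  )
  pharmacy <- c(
    paste(gen_pharmacies, "covid vaccine"),
    paste("covid vaccine", gen_pharmacies),
    paste("covid vaccine appointment", gen_pharmacies),
    paste(gen_pharmacies, "covid vaccine appointment")
  )
  composite <- as.vector(t(outer(
    gen_manufacturers[1:7], gen_pharmacies,
    function(m, p) paste(m, "covid vaccine", p)
  )))
  manufacturer <- c(
    paste(gen_manufacturers, "covid vaccine"),
    paste("covid vaccine", gen_manufacturers),
    paste(gen_manufacturers, "covid 19 vaccine"),
    paste("covid 19 vaccine", gen_manufacturers)
  )
  side_effects_safety <- c(
    "is the covid vaccine safe", "covid vaccine safety concerns",
    paste("covid vaccine", gen_se_terms),
    paste(gen_se_terms, "after covid vaccine"),
    paste("covid vaccine and", gen_se_terms)
  )
  myths_conspiracy <- c(
    "covid vaccine infertility", "does covid vaccine change dna",
    "covid vaccine microchip", "can i get covid from vaccine",
    "covid vaccine 5g", "covid vaccine dna", "covid vaccine and fertility",
    "can you get covid from the vaccine", "covid vaccine magnetic",
    "covid vaccine conspiracy", "covid vaccine hoax",
    "bill gates covid vaccine"
  )
  general_other <- c(
    "covid vaccine", "covid 19 vaccine", "coronavirus vaccine",
    "covid vaccination", "covid vax", "covid vaccine update",
    "covid vaccine news", "covid vaccination rates", "covid vaccine today",
    "covid vaccine info", "covid vaccine information", "covid vaccine facts",
    "covid vaccine results", "covid vaccine data", "covid vaccine statistics",
    "covid vaccine effectiveness", "covid vaccine efficacy",
    "covid vaccine dose", "covid vaccine doses", "covid vaccine booster",
    "covid vaccine second dose", "how long does covid vaccine last",
    "how does covid vaccine work", "covid vaccine tracker",
    "covid vaccine numbers", "covid vaccine timeline",
    "covid vaccine progress", "covid vaccine percentage",
    "covid vaccine count", "covid vaccine rate"
  )
  list(
    availability = availability, pharmacy = pharmacy, composite = composite,
    manufacturer = manufacturer, side_effects_safety = side_effects_safety,
    myths_conspiracy = myths_conspiracy, general_other = general_other
  )
}

gen_slot_categories <- list(
  availability = "availability",
  pharmacy = "availability",
  composite = c("availability", "manufacturer"),
  manufacturer = "manufacturer",
  side_effects_safety = "side_effects_safety",
  myths_conspiracy = "myths_conspiracy",
  general_other = "general_other"
)

#' Zipfian rank-frequency weights
#'
#' Normalized weights proportional to `rank^(-s)`: the heavy-tailed
#' rank-frequency law under which a small number of queries carries a large
#' share of total search volume.
#'
#' @param n Number of ranks (>= 1).
#' @param s Positive exponent; `s` near 0 approaches uniform, larger `s`
#'   concentrates mass in the head.
#' @return Numeric vector of length `n`, strictly decreasing, summing to 1.
#' @examples
#' zipf_weights(5, 1)
#' @export
zipf_weights <- function(n, s) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, is.numeric(s), s > 0)
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Configure the synthetic query-log generator
#'
#' Defines the statistical structure of a generated log: total daily volume,
#' Zipfian query popularity within each category universe, per-category
#' volume-share trajectories that are linear in week index (constant within
#' a week), a pharmacy sub-trajectory inside availability, an explicit
#' composite (manufacturer + pharmacy) multi-label rate, optional gold-label
#' flip noise for evaluation experiments, and optional per-day top-k
#' truncation. Configured shares partition expected volume: at every week
#' the four specific shares plus the implied general share sum to 1;
#' multi-label mass enters only through the composite templates.
#'
#' @param n_weeks Number of 7-day weeks (>= 1).
#' @param queries_per_day Expected (and exact, by multinomial sampling)
#'   total daily query volume.
#' @param start_date First calendar day of the log.
#' @param zipf_exponent Positive Zipf exponent for within-category query
#'   popularity.
#' @param shares Named list of `c(start, end)` share pairs for
#'   `availability`, `manufacturer`, `side_effects_safety`,
#'   `myths_conspiracy` (fractions of total volume; linearly interpolated
#'   across weeks). The general share is the weekly remainder.
#' @param pharmacy `c(start, end)` pharmacy share of *total* volume
#'   (a sub-trajectory of availability; must not exceed it).
#' @param composite_rate Fraction of pharmacy volume whose query also names
#'   a manufacturer, yielding gold set {availability, manufacturer}.
#' @param label_noise Probability in `[0, 1)` that a record's gold label is
#'   flipped to a uniformly chosen different category.
#' @param topk Optional per-day truncation to the `topk` highest-volume
#'   records ([daily_topk()]); `NULL` disables.
#' @param universe Named integer vector of distinct-query universe sizes per
#'   template slot (`availability`, `pharmacy`, `composite`, `manufacturer`,
#'   `side_effects_safety`, `myths_conspiracy`, `general_other`).
#' @param seed Master seed; all per-day, per-purpose random streams derive
#'   from it.
#' @return A validated `synthetic_config` object.
#' @seealso [study_scenario()] for the preset mirroring the study window.
#' @export
synthetic_config <- function(n_weeks = 10,
                             queries_per_day = 20000,
                             start_date = as.Date("2021-01-01"),
                             zipf_exponent = 1,
                             shares = list(
                               availability = c(0.62, 0.62),
                               manufacturer = c(0.104, 0.104),
                               side_effects_safety = c(0.057, 0.042),
                               myths_conspiracy = c(0.004, 0.001)
                             ),
                             pharmacy = c(0.059, 0.272),
                             composite_rate = 0.05,
                             label_noise = 0,
                             topk = NULL,
                             universe = c(
                               availability = 250, pharmacy = 36,
                               composite = 48, manufacturer = 30,
                               side_effects_safety = 36,
                               myths_conspiracy = 12, general_other = 30
                             ),
                             seed = 1L) {
  if (!is.numeric(n_weeks) || n_weeks < 1 || n_weeks != round(n_weeks)) {
    abort("n_weeks must be a positive integer", class = "vaxquery_config_error")
  }
  if (queries_per_day < 0) {
    abort("queries_per_day must be non-negative", class = "vaxquery_config_error")
  }
  if (zipf_exponent <= 0) {
    abort("zipf_exponent must be positive", class = "vaxquery_config_error")
  }
  if (label_noise < 0 || label_noise >= 1) {
    abort("label_noise must lie in [0, 1)", class = "vaxquery_config_error")
  }
  if (composite_rate < 0 || composite_rate > 1) {
    abort("composite_rate must lie in [0, 1]", class = "vaxquery_config_error")
  }
  need <- specific_categories()
  if (!all(need %in% names(shares))) {
    abort(paste0("shares must name: ", paste(need, collapse = ", ")),
      class = "vaxquery_config_error"
    )
  }
  endpoint <- function(i) {
    vapply(shares[need], `[`, numeric(1), i)
  }
  for (i in 1:2) {
    e <- endpoint(i)
    if (any(e < 0 | e > 1) || sum(e) > 1 + 1e-12) {
      abort("specific-category shares must lie in [0,1] and sum to <= 1 at both endpoints",
        class = "vaxquery_config_error"
      )
    }
    if (pharmacy[i] < 0 || pharmacy[i] > shares$availability[i]) {
      abort("pharmacy share must lie within [0, availability share] at both endpoints",
        class = "vaxquery_config_error"
      )
    }
  }
  cand <- gen_candidates()
  for (slot in names(universe)) {
    if (!slot %in% names(cand)) {
      abort(paste0("unknown universe slot: ", slot), class = "vaxquery_config_error")
    }
    if (universe[[slot]] < 1 || universe[[slot]] > length(cand[[slot]])) {
      abort(sprintf(
        "universe size for %s must lie in [1, %d]", slot, length(cand[[slot]])
      ), class = "vaxquery_config_error")
    }
  }
  structure(
    list(
      n_weeks = as.integer(n_weeks),
      queries_per_day = as.integer(queries_per_day),
      start_date = as.Date(start_date),
      zipf_exponent = zipf_exponent,
      shares = lapply(shares[need], as.numeric),
      pharmacy = as.numeric(pharmacy),
      composite_rate = composite_rate,
      label_noise = label_noise,
      topk = topk,
      universe = universe,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Preset emulating the 10-week study window
#'
#' A convenience configuration spanning ten 7-day weeks from 2021-01-01:
#' availability flat at 62% of volume with a pharmacy sub-share rising
#' linearly from 5.9% to 27.2%, manufacturer flat at 10.4%, side
#' effects/safety falling from 5.7% to 4.2%, myths/conspiracy falling from
#' 0.4% to 0.1%, the remainder general — the endpoint magnitudes the trend
#' analysis is designed to detect.
#'
#' @param queries_per_day Daily volume (default 50,000).
#' @param label_noise Gold-label flip rate (default 0).
#' @param seed Master seed.
#' @param ... Further overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
study_scenario <- function(queries_per_day = 50000, label_noise = 0,
                           seed = 1L, ...) {
  synthetic_config(
    n_weeks = 10,
    queries_per_day = queries_per_day,
    start_date = as.Date("2021-01-01"),
    shares = list(
      availability = c(0.62, 0.62),
      manufacturer = c(0.104, 0.104),
      side_effects_safety = c(0.057, 0.042),
      myths_conspiracy = c(0.004, 0.001)
    ),
    pharmacy = c(0.059, 0.272),
    label_noise = label_noise,
    seed = seed,
    ...
  )
}

# linear interpolation of a (start, end) share pair at week w (0-based)
share_at_week <- function(pair, w, n_weeks) {
  if (n_weeks == 1L) return(rep(pair[1], length(w)))
  pair[1] + (pair[2] - pair[1]) * w / (n_weeks - 1)
}

# expected slot masses for one week
slot_masses <- function(config, w) {
  a <- share_at_week(config$shares$availability, w, config$n_weeks)
  ph <- share_at_week(config$pharmacy, w, config$n_weeks)
  m <- share_at_week(config$shares$manufacturer, w, config$n_weeks)
  se <- share_at_week(config$shares$side_effects_safety, w, config$n_weeks)
  my <- share_at_week(config$shares$myths_conspiracy, w, config$n_weeks)
  g <- 1 - (a + m + se + my)
  if (g < -1e-12) {
    abort("specific shares exceed 1 at some week", class = "vaxquery_config_error")
  }
  c(
    availability = a - ph,
    pharmacy = ph * (1 - config$composite_rate),
    composite = ph * config$composite_rate,
    manufacturer = m,
    side_effects_safety = se,
    myths_conspiracy = my,
    general_other = max(g, 0)
  )
}

#' Analytic expected weekly shares of a generator configuration
#'
#' The measured (classifier-side) expectation of every weekly share under a
#' configuration: configured trajectories for availability, pharmacy, side
#' effects, myths and general; manufacturer additionally receives the
#' composite-template mass `composite_rate * pharmacy(week)` because
#' composite queries carry both availability and manufacturer labels.
#'
#' @param config A `synthetic_config`.
#' @return Tibble with `week_index` and one expected-share column per
#'   category plus `pharmacy`.
#' @export
expected_shares <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- seq_len(config$n_weeks) - 1L
  a <- share_at_week(config$shares$availability, w, config$n_weeks)
  ph <- share_at_week(config$pharmacy, w, config$n_weeks)
  m <- share_at_week(config$shares$manufacturer, w, config$n_weeks)
  se <- share_at_week(config$shares$side_effects_safety, w, config$n_weeks)
  my <- share_at_week(config$shares$myths_conspiracy, w, config$n_weeks)
  tibble::tibble(
    week_index = w,
    availability = a,
    manufacturer = m + config$composite_rate * ph,
    side_effects_safety = se,
    myths_conspiracy = my,
    general_other = 1 - (a + m + se + my),
    pharmacy = ph
  )
}

# deterministic per-(day, purpose) substream seed from the master seed;
# all operands stay exactly representable in doubles
substream_seed <- function(seed, day, purpose) {
  as.integer((as.numeric(seed) * 69069 + day * 1234567 + purpose * 97) %%
    2147483647)
}

#' Generate a gold-labeled synthetic query log
#'
#' Draws, for every day, exact multinomial daily volumes over a
#' category-partitioned Zipfian query universe whose category masses follow
#' the configured weekly share trajectories. Query strings come from
#' category template grammars over the shipped lexicon vocabulary, so each
#' string's gold label is its grammar category (composite templates yield
#' the multi-label set {availability, manufacturer} with the pharmacy flag).
#' Optional gold-label flip noise and per-day top-k truncation are applied
#' last. Output is fully reproducible: identical configuration and seed give
#' identical tibbles, and per-day/per-purpose substreams mean a change to
#' one aspect (e.g. the noise rate) does not perturb unrelated draws.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_log` list: `records` (tibble `date`, `query`,
#'   `count`), `gold` (tibble `date`, `query`, `categories` list column,
#'   `pharmacy`), the echoed `config`, and `version` info.
#' @export
generate_log <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  cand <- gen_candidates()
  slots <- names(config$universe)
  strings <- lapply(slots, function(s) cand[[s]][seq_len(config$universe[[s]])])
  names(strings) <- slots
  zipf <- lapply(slots, function(s) {
    zipf_weights(config$universe[[s]], config$zipf_exponent)
  })
  names(zipf) <- slots
  slot_of <- rep(slots, times = vapply(strings, length, integer(1)))
  all_strings <- unlist(strings, use.names = FALSE)

  n_days <- config$n_weeks * 7L
  days <- purrr::map(seq_len(n_days) - 1L, function(day) {
    w <- day %/% 7L
    mass <- slot_masses(config, w)
    prob <- unlist(
      lapply(slots, function(s) mass[[s]] * zipf[[s]]),
      use.names = FALSE
    )
    set.seed(substream_seed(config$seed, day, 1L))
    counts <- as.vector(rmultinom(1, size = config$queries_per_day, prob = prob))
    keep <- counts > 0L
    if (!any(keep)) return(NULL)
    day_tbl <- tibble::tibble(
      date = config$start_date + day,
      query = all_strings[keep],
      count = counts[keep],
      slot = slot_of[keep]
    )
    day_tbl$categories <- unname(gen_slot_categories[day_tbl$slot])
    day_tbl$pharmacy <- day_tbl$slot %in% c("pharmacy", "composite")
    if (config$label_noise > 0) {
      set.seed(substream_seed(config$seed, day, 2L))
      flip <- runif(nrow(day_tbl)) < config$label_noise
      if (any(flip)) {
        for (i in which(flip)) {
          primary <- day_tbl$categories[[i]][1]
          pool <- setdiff(vax_categories, primary)
          day_tbl$categories[[i]] <- pool[sample.int(length(pool), 1L)]
        }
        day_tbl$pharmacy[flip] <- FALSE
      }
    }
    day_tbl
  })
  log <- dplyr::bind_rows(days)
  if (nrow(log) == 0) {
    log <- tibble::tibble(
      date = as.Date(character()), query = character(),
      count = integer(), slot = character(),
      categories = list(), pharmacy = logical()
    )
  }
  if (!is.null(config$topk)) {
    log <- daily_topk(log, config$topk)
  }
  structure(
    list(
      records = dplyr::select(log, "date", "query", "count"),
      gold = dplyr::select(log, "date", "query", "categories", "pharmacy"),
      config = config,
      version = list(
        package = as.character(utils::packageVersion("vaxquery")),
        grammar = "1.0.0"
      )
    ),
    class = "synthetic_log"
  )
}

#' @export
print.synthetic_log <- function(x, ...) {
  cat(sprintf(
    "<synthetic_log> %d records over %d days (%s to %s), %s total volume\n",
    nrow(x$records), x$config$n_weeks * 7L,
    format(x$config$start_date),
    format(x$config$start_date + x$config$n_weeks * 7L - 1L),
    format(sum(x$records$count), big.mark = ",")
  ))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d weeks from %s, %d queries/day, zipf s = %g, noise = %g, seed = %d\n",
    x$n_weeks, format(x$start_date), x$queries_per_day, x$zipf_exponent,
    x$label_noise, x$seed
  ))
  shr <- function(p) sprintf("%.3f -> %.3f", p[1], p[2])
  for (cc in names(x$shares)) cat(sprintf("  %-20s %s\n", cc, shr(x$shares[[cc]])))
  cat(sprintf("  %-20s %s (composite rate %.2f)\n", "pharmacy", shr(x$pharmacy), x$composite_rate))
  invisible(x)
}
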
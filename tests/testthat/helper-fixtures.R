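# shared fixtures and independent brute-force oracles

# tiny hand-built lexicon for unit tests that should not depend on the
# shipped vocabulary
mini_lexicon <- function(extra_availability = character(0)) {
  vax_lexicon(
    categories = list(
      availability = c("cvs", "near me", "texas", extra_availability),
      manufacturer = c("pfizer", "moderna"),
      side_effects_safety = c("side effects", "fever"),
      myths_conspiracy = c("microchip", "covid from vaccine")
    ),
    pharmacy_names = "cvs",
    filter_terms = list(
      covid = c("covid", "coronavirus"),
      vaccine = c("vaccine", "vaccination", "vaccinated", "vax")
    ),
    variants = c(vaccines = "vaccine", phizer = "pfizer", effect = "effects"),
    general_patterns = c("covid vaccine", "covid 19 vaccine"),
    version = "test"
  )
}

# every example query from the category table, with its row's category
table1_queries <- function() {
  tibble::tribble(
    ~query, ~category,
    "ny covid vaccine", "availability",
    "covid vaccine california", "availability",
    "florida covid vaccine", "availability",
    "covid vaccine near me", "availability",
    "where to get covid vaccine", "availability",
    "cvs covid vaccine", "availability",
    "covid vaccine rite-aid", "availability",
    "covid vaccine appointment", "availability",
    "when can I get covid vaccine", "availability",
    "pfizer vaccine", "manufacturer",
    "moderna vaccine", "manufacturer",
    "johnson vaccine", "manufacturer",
    "j&j vaccine", "manufacturer",
    "covid vaccine side effects", "side_effects_safety",
    "covid vaccine safety", "side_effects_safety",
    "reaction to covid vaccine", "side_effects_safety",
    "pregnant women covid vaccine", "side_effects_safety",
    "covid vaccine blood clot", "side_effects_safety",
    "problems with covid vaccine", "side_effects_safety",
    "covid vaccine fever", "side_effects_safety",
    "covid vaccine allergy", "side_effects_safety",
    "covid vaccine infertility", "myths_conspiracy",
    "does covid vaccine change dna", "myths_conspiracy",
    "covid vaccine microchip", "myths_conspiracy",
    "can I get covid from vaccine", "myths_conspiracy",
    "covid vaccine 5G", "myths_conspiracy",
    "covid vaccine", "general_other",
    "covid-19 vaccine", "general_other",
    "coronavirus vaccine", "general_other",
    "covid vaccine update", "general_other",
    "covid vaccination rates", "general_other"
  )
}

# closed-form two-parameter least squares with slope t-test (the oracle for
# fit_trend; kept independent of lm)
ols_oracle <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  intercept <- mean(y) - beta * mean(t)
  r2 <- sxy^2 / (sxx * syy)
  sse <- syy - beta * sxy
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- beta / se
  list(
    beta = beta, intercept = intercept, r_squared = r2,
    df = n - 2L, p_value = 2 * stats::pt(-abs(tstat), n - 2)
  )
}

# brute-force per-day top-k (sort oracle)
topk_oracle <- function(data, k) {
  out <- lapply(split(data, data$date), function(d) {
    d <- d[order(-d$count, d$query), , drop = FALSE]
    utils::head(d, k)
  })
  res <- dplyr::bind_rows(out)
  rownames(res) <- NULL
  res[order(res$date, -res$count, res$query), ]
}

# independent double-loop confusion tally (oracle for precision_recall)
confusion_oracle <- function(predicted, gold, labels) {
  key <- function(d) paste(d$date, d$query)
  gold <- gold[match(key(predicted), key(gold)), ]
  counts <- list()
  for (lab in labels) {
    tp <- fp <- fn <- 0L
    for (i in seq_len(nrow(predicted))) {
      if (lab == "pharmacy") {
        p <- isTRUE(as.logical(predicted$pharmacy[i]))
        g <- isTRUE(as.logical(gold$pharmacy[i]))
      } else {
        p <- lab %in% predicted$categories[[i]]
        g <- lab %in% gold$categories[[i]]
      }
      if (p && g) tp <- tp + 1L
      if (p && !g) fp <- fp + 1L
      if (!p && g) fn <- fn + 1L
    }
    counts[[lab]] <- c(tp = tp, fp = fp, fn = fn)
  }
  counts
}

# random small classified/gold pair with injected disagreements
random_labelled_set <- function(n, seed) {
  withr::with_seed(seed, {
    cats <- vax_categories
    queries <- paste0("q", seq_len(n))
    dates <- as.Date("2021-01-01") + sample(0:6, n, replace = TRUE)
    pick <- function() {
      if (runif(1) < 0.2) {
        sample(cats[1:4], 2)
      } else {
        sample(cats, 1)
      }
    }
    gold_cats <- replicate(n, pick(), simplify = FALSE)
    pred_cats <- lapply(gold_cats, function(cc) {
      if (runif(1) < 0.3) {
        sample(cats, 1)
      } else {
        cc
      }
    })
    gold_ph <- vapply(gold_cats, function(cc) "availability" %in% cc && runif(1) < 0.5, logical(1))
    pred_ph <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.2) !gold_ph[i] else gold_ph[i]
    }, logical(1))
    pred_ph <- pred_ph & vapply(pred_cats, function(cc) "availability" %in% cc, logical(1))
    gold_ph <- gold_ph & vapply(gold_cats, function(cc) "availability" %in% cc, logical(1))
    list(
      predicted = tibble::tibble(
        date = dates, query = queries, categories = pred_cats, pharmacy = pred_ph
      ),
      gold = tibble::tibble(
        date = dates, query = queries, categories = gold_cats, pharmacy = gold_ph
      )
    )
  })
}

harmonic <- function(n, s = 1) sum(seq_len(n)^(-s))
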
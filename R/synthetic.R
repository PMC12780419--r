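#' Specification for a synthetic visit corpus
#'
#' Declares the generative parameters of a seeded synthetic primary-care
#' corpus with known ground truth. Defaults emulate the validation cohort's
#' structure: 200 children, about 50 visits each (negative-binomial counts
#' with mild overdispersion), and a 9% prevalence of visits where OM was
#' considered. Negative visits are decorated, on disjoint subsets, with the
#' documented false-positive/negation constructions: a search term negated
#' by an adjacent exclusion word ("TM normal"), an ambiguous abbreviation
#' used non-otologically ("ROM" as range of movement), and a family-member
#' mention ("brother has otitis media"). Character-level misspellings are
#' applied to filler text only — planted constructions stay verbatim, since
#' the matcher is exact by design (set `corrupt_planted_terms = TRUE` to
#' demonstrate the resulting sensitivity loss).
#'
#' @param seed integer RNG seed. Required: all generator randomness is
#'   seeded, no hidden entropy.
#' @param n_children number of children (default 200).
#' @param mean_visits_per_child mean visits per child (default 50).
#' @param dispersion negative-binomial size parameter for visits per child
#'   (default 25; larger = closer to Poisson).
#' @param prevalence probability a visit is OM-considered (default 0.09).
#' @param term_weights optional named numeric vector of relative sampling
#'   frequencies over lexicon search-term surfaces for planted terms;
#'   default uniform. Unknown names are an error at generation time.
#' @param negation_rate probability a negative visit carries a
#'   term-plus-exclusion construction (default 0.15).
#' @param confounder_rate probability a negative visit uses an ambiguous
#'   abbreviation non-otologically (default 0.03).
#' @param family_mention_rate probability a negative visit mentions OM in a
#'   relative (default 0.01).
#' @param misspelling_rate per-character typo probability on filler text
#'   (default 0.01).
#' @param corrupt_planted_terms also apply typos to planted search terms
#'   (default FALSE).
#' @return An `om_synth_spec`.
#' @export
synthetic_corpus_spec <- function(seed,
                                  n_children = 200L,
                                  mean_visits_per_child = 50,
                                  dispersion = 25,
                                  prevalence = 0.09,
                                  term_weights = NULL,
                                  negation_rate = 0.15,
                                  confounder_rate = 0.03,
                                  family_mention_rate = 0.01,
                                  misspelling_rate = 0.01,
                                  corrupt_planted_terms = FALSE) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("synthetic_corpus_spec: an explicit integer seed is required",
         call. = FALSE)
  }
  rates <- c(prevalence = prevalence, negation_rate = negation_rate,
             confounder_rate = confounder_rate,
             family_mention_rate = family_mention_rate,
             misspelling_rate = misspelling_rate)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (negation_rate + confounder_rate + family_mention_rate > 1) {
    stop("negation + confounder + family rates must not exceed 1 ",
         "(they partition the negative visits)", call. = FALSE)
  }
  if (n_children < 1L) stop("n_children must be >= 1", call. = FALSE)
  if (mean_visits_per_child <= 0) {
    stop("mean_visits_per_child must be > 0", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_children = as.integer(n_children),
         mean_visits_per_child = mean_visits_per_child,
         dispersion = dispersion, prevalence = prevalence,
         term_weights = term_weights, negation_rate = negation_rate,
         confounder_rate = confounder_rate,
         family_mention_rate = family_mention_rate,
         misspelling_rate = misspelling_rate,
         corrupt_planted_terms = isTRUE(corrupt_planted_terms)),
    class = "om_synth_spec"
  )
}

#' @export
print.om_synth_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<om_synth_spec> seed=%d, %d children x ~%.0f visits, prevalence=%.3f\n",
    "  negation=%.3f confounder=%.3f family=%.3f misspelling=%.3f\n"),
    x$seed, x$n_children, x$mean_visits_per_child, x$prevalence,
    x$negation_rate, x$confounder_rate, x$family_mention_rate,
    x$misspelling_rate))
  invisible(x)
}

# Template pools. Filler sentences are constructed to contain no seed
# lexicon term or exclusion word; a generation-time assertion re-checks
# against whatever lexicon is actually supplied and falls back to
# uncorrupted/clean filler if a typo or template accidentally collides.
filler_pool <- c(
  "Cough and coryza for three days, chest sounds good.",
  "Immunisations given as scheduled, no concerns raised.",
  "Mild fever overnight, settled with paracetamol.",
  "Feeding well, weight tracking along centile.",
  "Rash on trunk, blanching, likely viral exanthem.",
  "Runny nose and sneezing, advised saline drops.",
  "Review of eczema, emollients continued.",
  "Sore throat, tonsils slightly enlarged, viral picture.",
  "Vomited twice yesterday, hydration adequate.",
  "Attending daycare, several contacts with colds.",
  "Sleep settled and appetite returning.",
  "Follow up arranged with the practice nurse."
)

positive_pool <- c(
  "Pulling at right ear, drum red and bulging. %s diagnosed, started amoxicillin.",
  "Irritable and febrile overnight. Impression: %s.",
  "Left drum dull and injected, consistent with %s. Review 48h.",
  "Seen with ear pain, %s on examination, analgesia advised."
)

# term then exclusion word, strictly adjacent, so the construction is
# suppressed under every combination-policy mode
negation_pool <- c(
  "Ears examined, %s %s bilaterally.",
  "%s %s on examination today.",
  "Checked both ears, %s %s."
)

confounder_pool <- c(
  "Knee injury at kindy, ROM improving since physio.",
  "Shoulder strain, ROM reduced, physio referral made.",
  "Ankle sprain review, full ROM returning."
)

family_pool <- c(
  "Mother reports brother has %s, index child well today.",
  "Sister treated for %s last week, checking sibling.",
  "Family history: father had %s as a young child."
)

corrupt_text <- function(text, rate) {
  if (rate <= 0 || !nzchar(text)) return(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  target <- grepl("[[:alpha:]]", chars)
  hit <- target & stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(letters, sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic corpus
#'
#' Deterministic for a fixed spec (byte-identical corpora for the same
#' seed). Gold labels reflect construction truth only — a visit is gold
#' positive if and only if an affirmative OM construction was planted — and
#' never depend on matcher output, so no label leakage is possible.
#' Positive visits embed one exact search-term occurrence in an affirmative
#' sentence guaranteed free of in-scope exclusion words; filler text is
#' asserted free of accidental lexicon hits (typos that create one are
#' rolled back).
#'
#' @param spec an [synthetic_corpus_spec()].
#' @param lx the lexicon whose terms are planted. When
#'   `confounder_rate > 0`, the lexicon must contain the ambiguous
#'   abbreviation "ROM" (its musculoskeletal reading is the planted
#'   confounder).
#' @return An `om_corpus`: list with `records` (data.frame child_id,
#'   visit_id, visit_date, text), `gold` (visit_id, om_considered) and
#'   `provenance` (visit_id, construction, planted_term,
#'   planted_exclusion).
#' @export
generate_corpus <- function(spec, lx) {
  stopifnot(inherits(spec, "om_synth_spec"))
  validate_lexicon(lx)

  surfaces <- lx$search_terms$surface
  weights <- rep(1, length(surfaces))
  if (!is.null(spec$term_weights)) {
    unknown <- setdiff(names(spec$term_weights), surfaces)
    if (length(unknown)) {
      stop("term_weights reference unknown terms: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    weights <- spec$term_weights[match(surfaces, names(spec$term_weights))]
    weights[is.na(weights)] <- 0
    if (sum(weights) <= 0) stop("term_weights sum to zero", call. = FALSE)
  }
  if (spec$confounder_rate > 0 && !"ROM" %in% surfaces) {
    stop("confounder_rate > 0 requires the ambiguous abbreviation 'ROM' ",
         "in the lexicon", call. = FALSE)
  }
  excl <- lx$exclusion_words$surface

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  # phase 1: structure and labels -- consumes RNG independently of the
  # lexicon content, so gold is invariant to the lexicon supplied
  n_visits_per_child <- pmax(1L, stats::rnbinom(
    spec$n_children, size = spec$dispersion,
    mu = spec$mean_visits_per_child))
  n <- sum(n_visits_per_child)
  child_idx <- rep(seq_len(spec$n_children), n_visits_per_child)
  is_positive <- stats::runif(n) < spec$prevalence
  u <- stats::runif(n)
  construction <- ifelse(
    is_positive, "positive",
    ifelse(u < spec$negation_rate, "negation",
    ifelse(u < spec$negation_rate + spec$confounder_rate, "confounder",
    ifelse(u < spec$negation_rate + spec$confounder_rate +
             spec$family_mention_rate, "family", "filler"))))
  offsets <- sample.int(3650L, n, replace = TRUE)  # visits over ~10 years

  # phase 2: text
  texts <- character(n)
  planted_term <- rep(NA_character_, n)
  planted_excl <- rep(NA_character_, n)
  draw_term <- function() sample(surfaces, 1L, prob = weights)

  for (i in seq_len(n)) {
    filler <- paste(sample(filler_pool, sample.int(3L, 1L)),
                    collapse = " ")
    typo <- corrupt_text(filler, spec$misspelling_rate)
    # roll back typos that accidentally create a lexicon hit
    filler_used <- if (nrow(find_term_occurrences(typo, lx)) == 0L) typo
                   else filler
    kind <- construction[i]
    if (kind == "positive") {
      t <- draw_term()
      if (spec$corrupt_planted_terms) t <- corrupt_text(t,
                                                        spec$misspelling_rate)
      planted_term[i] <- t
      body <- sprintf(sample(positive_pool, 1L), t)
      text <- paste(filler_used, body)
      # construction guarantee: the planted term must survive screening
      # (a filler typo may have produced an in-scope exclusion word)
      if (!spec$corrupt_planted_terms &&
          !screen_visit(list(visit_id = "tmp", text = text), lx)$flagged) {
        text <- paste(filler, body)
      }
    } else if (kind == "negation" && length(excl)) {
      t <- draw_term()
      e <- sample(excl, 1L)
      planted_term[i] <- t
      planted_excl[i] <- e
      text <- paste(filler_used, sprintf(sample(negation_pool, 1L), t, e))
      if (screen_visit(list(visit_id = "tmp", text = text), lx)$flagged) {
        text <- paste(filler, sprintf(negation_pool[2], t, e))
      }
    } else if (kind == "confounder") {
      planted_term[i] <- "ROM"
      text <- paste(filler_used, sample(confounder_pool, 1L))
    } else if (kind == "family") {
      t <- draw_term()
      planted_term[i] <- t
      text <- paste(filler_used, sprintf(sample(family_pool, 1L), t))
    } else {
      if (kind == "negation") construction[i] <- "filler"  # no excl words
      text <- filler_used
    }
    texts[i] <- text
  }

  visit_id <- sprintf("v%05d", seq_len(n))
  structure(
    list(
      records = data.frame(
        child_id = sprintf("c%03d", child_idx),
        visit_id = visit_id,
        visit_date = format(as.Date("2010-01-01") + offsets, "%Y-%m-%d"),
        text = texts, stringsAsFactors = FALSE
      ),
      gold = data.frame(visit_id = visit_id, om_considered = is_positive,
                        stringsAsFactors = FALSE),
      provenance = data.frame(
        visit_id = visit_id, construction = construction,
        planted_term = planted_term, planted_exclusion = planted_excl,
        stringsAsFactors = FALSE
      ),
      spec = spec
    ),
    class = "om_corpus"
  )
}

#' @export
print.om_corpus <- function(x, ...) {
  cat(sprintf("<om_corpus> %d visits / %d children, %d gold-positive\n",
              nrow(x$records), length(unique(x$records$child_id)),
              sum(x$gold$om_considered)))
  invisible(x)
}

#' Summarize a corpus in the shape of a cohort table
#'
#' @param corpus an `om_corpus` (or any list with `records` and `gold`).
#' @return An `om_corpus_summary` list: n_children, n_visits, visits per
#'   child (min/median/mean/max), n_om_considered, pct_om_considered.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(is.data.frame(corpus$records), is.data.frame(corpus$gold))
  per_child <- table(corpus$records$child_id)
  n_pos <- sum(corpus$gold$om_considered)
  structure(
    list(
      n_children = length(per_child),
      n_visits = nrow(corpus$records),
      visits_per_child = c(min = min(per_child),
                           median = stats::median(per_child),
                           mean = mean(per_child), max = max(per_child)),
      n_om_considered = n_pos,
      pct_om_considered = 100 * n_pos / nrow(corpus$records)
    ),
    class = "om_corpus_summary"
  )
}

#' @export
print.om_corpus_summary <- function(x, ...) {
  cat("Synthetic corpus summary\n")
  cat(sprintf("  children                 %d\n", x$n_children))
  cat(sprintf("  primary care visits      %d\n", x$n_visits))
  cat(sprintf("  visits per child         min %d, median %.0f, mean %.1f, max %d\n",
              x$visits_per_child["min"], x$visits_per_child["median"],
              x$visits_per_child["mean"], x$visits_per_child["max"]))
  cat(sprintf("  OM-considered visits     %d (%.1f%%)\n",
              x$n_om_considered, x$pct_om_considered))
  invisible(x)
}

#' End-to-end closed-loop validation on synthetic data
#'
#' Generates a corpus, screens it with the same lexicon, evaluates against
#' the known gold labels and returns the full diagnostic panel. With a
#' noise-free spec (all construction rates zero, exact planted terms) the
#' screen is perfect by construction: sensitivity = specificity = 100%.
#'
#' @param spec an [synthetic_corpus_spec()].
#' @param lx the lexicon.
#' @param level confidence level (default 0.95).
#' @return An `om_diagnostics` with the generated `om_corpus` attached as
#'   attribute `"corpus"`.
#' @export
closed_loop_check <- function(spec, lx, level = 0.95) {
  corpus <- generate_corpus(spec, lx)
  screen <- screen_corpus(corpus$records, lx)
  stats <- diagnostic_stats(build_confusion(screen, corpus$gold), level)
  attr(stats, "corpus") <- corpus
  attr(stats, "screen") <- screen
  stats
}
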
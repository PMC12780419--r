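#' Find boundary-respecting occurrences of every search term
#'
#' Scans raw visit text for exact (per-term case rule) occurrences of each
#' lexicon search term. An occurrence at character positions `start..end`
#' (1-based, inclusive, `substr()` semantics) qualifies only if the
#' characters immediately before `start` and after `end`, when they exist,
#' are not alphanumeric — so the abbreviation `tm` never fires inside
#' "treatment", while `T/M` matches with its literal slash. Overlapping
#' occurrences of different terms are all reported. No normalization is
#' applied: matching runs against the stored note byte-for-byte.
#'
#' @param text a single character string (may be empty).
#' @param lx a valid [lexicon()].
#' @return A data.frame of matches ordered by (start, end): columns
#'   `surface`, `case_sensitive`, `start`, `end`, `excluded` (all `FALSE`
#'   here), `excl_surface`, `excl_start`, `excl_end` (all `NA` here).
#' @export
find_term_occurrences <- function(text, lx) {
  validate_lexicon(lx)
  locate_surfaces(text, lx$search_terms)
}

# Shared fixed-string locator with the word-boundary rule; used for both
# search terms and exclusion words.
locate_surfaces <- function(text, terms) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(
    surface = character(0), case_sensitive = logical(0),
    start = integer(0), end = integer(0), excluded = logical(0),
    excl_surface = character(0), excl_start = integer(0),
    excl_end = integer(0), stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(text) || nrow(terms) == 0L) return(empty)

  n <- nchar(text)
  rows <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    surf <- terms$surface[i]
    loc <- stringi::stri_locate_all_fixed(
      text, surf, overlap = TRUE,
      opts_fixed = stringi::stri_opts_fixed(
        case_insensitive = !terms$case_sensitive[i])
    )[[1]]
    if (all(is.na(loc[, 1]))) next
    starts <- loc[, 1]
    ends <- loc[, 2]
    ok_before <- starts == 1L |
      !is_alnum_char(substring(text, starts - 1L, starts - 1L))
    ok_after <- ends == n |
      !is_alnum_char(substring(text, ends + 1L, ends + 1L))
    keep <- ok_before & ok_after
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      surface = surf, case_sensitive = terms$case_sensitive[i],
      start = as.integer(starts[keep]), end = as.integer(ends[keep]),
      excluded = FALSE, excl_surface = NA_character_,
      excl_start = NA_integer_, excl_end = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  # the same surface may be listed under both case rules; report each
  # (surface, start) at most once, keeping lexicon order
  out <- out[!duplicated(paste(out$surface, out$start, sep = "\r")), ,
             drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_alnum_char <- function(ch) grepl("^[[:alnum:]]$", ch)

#' Tokenize clinical note text
#'
#' Tokens are maximal runs of alphanumeric characters, allowing an internal
#' `/` between alphanumeric runs so the tympanic-membrane form `T/M` is a
#' single token. Everything else (whitespace, punctuation) separates tokens.
#'
#' @param text single character string.
#' @return data.frame with columns `token`, `start`, `end` (1-based,
#'   inclusive).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  loc <- stringi::stri_locate_all_regex(
    text, "[[:alnum:]]+(?:/[[:alnum:]]+)*")[[1]]
  if (all(is.na(loc[, 1]))) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    token = substring(text, loc[, 1], loc[, 2]),
    start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
    stringsAsFactors = FALSE
  )
}

# Sentence id for each character position: boundaries are '.', '!', '?' and
# newline; the boundary character closes its sentence.
sentence_ids <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_bound <- chars %in% c(".", "!", "?", "\n")
  c(0L, cumsum(is_bound))[seq_along(chars)] + 1L
}

# Token index range [lo, hi] of tokens overlapping character span
# [start, end]; NA when the span touches no token (cannot happen for a
# term occurrence, which is alphanumeric-anchored).
token_range <- function(tokens, start, end) {
  hit <- which(tokens$start <= end & tokens$end >= start)
  if (!length(hit)) return(c(NA_integer_, NA_integer_))
  c(min(hit), max(hit))
}

#' Apply the exclusion-combination rule to found matches
#'
#' Each found search term is compared to every exclusion word: when an
#' exclusion word occurs within the combination policy's scope of the match
#' (see [combination_policy()]), the match is marked excluded and
#' `excl_surface`/`excl_start`/`excl_end` record the nearest qualifying
#' exclusion occurrence (by character distance; ties broken by the earlier
#' offset). Exclusion is per match: a suppressed "TM normal" finding leaves
#' an independent "AOM" match elsewhere in the same note untouched.
#'
#' @param text the visit text the matches came from.
#' @param matches data.frame from [find_term_occurrences()].
#' @param lx the same lexicon.
#' @return `matches` with `excluded` and the `excl_*` columns filled in.
#' @export
apply_exclusion_rules <- function(text, matches, lx) {
  validate_lexicon(lx)
  stopifnot(is.data.frame(matches))
  if (nrow(matches) == 0L) return(matches)

  # integrity: every span must reproduce its surface under its case rule
  got <- substr(rep(text, nrow(matches)), matches$start, matches$end)
  same <- ifelse(matches$case_sensitive, got == matches$surface,
                 tolower(got) == tolower(matches$surface))
  if (!all(same)) {
    stop("match spans inconsistent with text (integrity error)",
         call. = FALSE)
  }

  if (nrow(lx$exclusion_words) == 0L) return(matches)
  excl <- locate_surfaces(text, lx$exclusion_words)
  if (nrow(excl) == 0L) return(matches)

  policy <- lx$policy
  tokens <- tokenize_text(text)
  sids <- if (policy$mode == "sentence") sentence_ids(text) else NULL

  for (m in seq_len(nrow(matches))) {
    m_tok <- token_range(tokens, matches$start[m], matches$end[m])
    qualifying <- logical(nrow(excl))
    for (e in seq_len(nrow(excl))) {
      qualifying[e] <- scope_qualifies(
        policy,
        m_tok, matches$start[m], matches$end[m],
        token_range(tokens, excl$start[e], excl$end[e]),
        excl$start[e], excl$end[e],
        sids
      )
    }
    if (any(qualifying)) {
      cand <- which(qualifying)
      cdist <- char_distance(matches$start[m], matches$end[m],
                             excl$start[cand], excl$end[cand])
      best <- cand[order(cdist, excl$start[cand])][1]
      matches$excluded[m] <- TRUE
      matches$excl_surface[m] <- excl$surface[best]
      matches$excl_start[m] <- excl$start[best]
      matches$excl_end[m] <- excl$end[best]
    }
  }
  matches
}

# Character gap between two inclusive spans (0 when overlapping/adjacent).
char_distance <- function(m_start, m_end, e_start, e_end) {
  pmax(0L, pmax(e_start - m_end, m_start - e_end) - 1L)
}

scope_qualifies <- function(policy, m_tok, m_start, m_end,
                            e_tok, e_start, e_end, sids) {
  if (policy$mode == "record") return(TRUE)
  if (policy$mode == "sentence") {
    return(sids[m_start] == sids[e_start])
  }
  # token-distance modes; direction matters unless bidirectional
  if (any(is.na(m_tok)) || any(is.na(e_tok))) return(FALSE)
  if (e_tok[1] > m_tok[2]) {        # exclusion after the term
    dist <- e_tok[1] - m_tok[2]
  } else if (e_tok[2] < m_tok[1]) { # exclusion before the term
    if (!policy$bidirectional) return(FALSE)
    dist <- m_tok[1] - e_tok[2]
  } else {
    dist <- 0L                      # overlapping tokens
  }
  limit <- if (policy$mode == "phrase") 1L else policy$window_tokens
  dist <= limit
}

#' Screen a single visit record
#'
#' Composes [find_term_occurrences()] and [apply_exclusion_rules()] and
#' classifies the visit: it is flagged ("OM considered") if and only if at
#' least one term occurrence survives the exclusion stage. Deterministic —
#' identical inputs always give identical output. Contextual false
#' positives ("brother has otitis media", "ROM" as range of movement) are
#' flagged by design and left to the downstream clinician review.
#'
#' @param record a list or one-row data.frame with at least `visit_id` and
#'   `text` (optionally `child_id`, `visit_date`).
#' @param lx a valid lexicon.
#' @return An `om_screen_result`: list with `visit_id`, `flagged`, and the
#'   `matches` data.frame (ordered by start, then end).
#' @export
screen_visit <- function(record, lx) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  text <- record$text
  if (is.null(text) || length(text) != 1L || is.na(text)) text <- ""
  matches <- apply_exclusion_rules(text, find_term_occurrences(text, lx), lx)
  structure(
    list(visit_id = as.character(record$visit_id),
         flagged = any(!matches$excluded),
         matches = matches),
    class = "om_screen_result"
  )
}

#' @export
print.om_screen_result <- function(x, ...) {
  cat(sprintf("<om_screen_result> visit %s: %s (%d match(es), %d excluded)\n",
              x$visit_id, if (x$flagged) "FLAGGED" else "not flagged",
              nrow(x$matches), sum(x$matches$excluded)))
  invisible(x)
}

#' Screen a corpus of visit records
#'
#' One result per record, input order preserved. Every excluded match is
#' recorded in an audit table (visit id, term, exclusion word, spans) so a
#' reviewer can reconstruct why each suppression happened.
#'
#' @param records data.frame of visit records with columns `child_id`,
#'   `visit_id`, `visit_date`, `text` (see [read_visit_records()]).
#' @param lx a valid lexicon.
#' @param verbose emit one message per excluded match.
#' @return An `om_screen_set`: list with `results` (list of
#'   `om_screen_result`), `flags` (data.frame visit_id/flagged) and `audit`
#'   (data.frame of excluded matches).
#' @export
screen_corpus <- function(records, lx, verbose = FALSE) {
  stopifnot(is.data.frame(records), "visit_id" %in% names(records),
            "text" %in% names(records))
  dup <- unique(records$visit_id[duplicated(records$visit_id)])
  if (length(dup)) {
    stop("duplicate visit_id in corpus: ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  validate_lexicon(lx)

  results <- vector("list", nrow(records))
  audit <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- screen_visit(records[i, , drop = FALSE], lx)
    results[[i]] <- res
    exc <- res$matches[res$matches$excluded, , drop = FALSE]
    if (nrow(exc)) {
      audit[[i]] <- data.frame(
        visit_id = res$visit_id, surface = exc$surface,
        start = exc$start, end = exc$end,
        excl_surface = exc$excl_surface, excl_start = exc$excl_start,
        excl_end = exc$excl_end, stringsAsFactors = FALSE
      )
      if (verbose) {
        for (j in seq_len(nrow(exc))) {
          message(sprintf(
            "excluded: visit %s term '%s' [%d,%d] by '%s' [%d,%d]",
            res$visit_id, exc$surface[j], exc$start[j], exc$end[j],
            exc$excl_surface[j], exc$excl_start[j], exc$excl_end[j]))
        }
      }
    }
  }
  audit <- do.call(rbind, Filter(Negate(is.null), audit))
  if (is.null(audit)) {
    audit <- data.frame(visit_id = character(0), surface = character(0),
                        start = integer(0), end = integer(0),
                        excl_surface = character(0), excl_start = integer(0),
                        excl_end = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(
      results = results,
      flags = data.frame(
        visit_id = vapply(results, `[[`, character(1), "visit_id"),
        flagged = vapply(results, `[[`, logical(1), "flagged"),
        stringsAsFactors = FALSE
      ),
      audit = audit
    ),
    class = "om_screen_set"
  )
}

#' @export
print.om_screen_set <- function(x, ...) {
  cat(sprintf("<om_screen_set> %d visits, %d flagged, %d excluded matches\n",
              nrow(x$flags), sum(x$flags$flagged), nrow(x$audit)))
  invisible(x)
}
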
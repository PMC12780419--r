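#' Adjudicate independent reviewer labels
#'
#' Models the consensus stage of a multi-reviewer chart review. Visits on
#' which all reviewers agree adopt the shared label with status
#' `unanimous`. Discordant visits adopt a supplied resolution
#' (status `consensus_resolved`); without one they remain `unresolved` —
#' there is no automatic majority vote, because the original workflow
#' resolved disagreement by discussion against the term list, not by
#' arithmetic.
#'
#' @param labels data.frame with columns `visit_id`, `reviewer_id`,
#'   `om_considered` (logical); every visit needs at least two reviewers.
#' @param resolutions optional data.frame with `visit_id`, `om_considered`,
#'   referencing only discordant visits.
#' @return data.frame with columns `visit_id`, `status`
#'   (unanimous/consensus_resolved/unresolved) and `om_considered`
#'   (`NA` when unresolved), one row per visit, in first-appearance order.
#' @export
adjudicate <- function(labels, resolutions = NULL) {
  stopifnot(is.data.frame(labels),
            all(c("visit_id", "reviewer_id", "om_considered") %in%
                  names(labels)))
  key <- paste(labels$visit_id, labels$reviewer_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (visit_id, reviewer_id) label", call. = FALSE)
  }
  ids <- unique(labels$visit_id)
  n_rev <- table(labels$visit_id)[ids]
  if (any(n_rev < 2)) {
    stop("adjudication needs >= 2 reviewers per visit; short: ",
         paste(sQuote(ids[n_rev < 2]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(resolutions)) {
    stopifnot(all(c("visit_id", "om_considered") %in% names(resolutions)))
    if (anyDuplicated(resolutions$visit_id)) {
      stop("duplicate resolution for visit(s) ",
           paste(sQuote(unique(resolutions$visit_id[
             duplicated(resolutions$visit_id)])), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(resolutions$visit_id, ids)
    if (length(unknown)) {
      stop("resolution for unknown visit(s) ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
  }
  out <- data.frame(visit_id = ids, status = NA_character_,
                    om_considered = NA, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    votes <- labels$om_considered[labels$visit_id == ids[i]]
    if (all(votes) || all(!votes)) {
      if (!is.null(resolutions) && ids[i] %in% resolutions$visit_id) {
        stop("resolution supplied for unanimous visit ", sQuote(ids[i]),
             call. = FALSE)
      }
      out$status[i] <- "unanimous"
      out$om_considered[i] <- votes[1]
    } else if (!is.null(resolutions) && ids[i] %in% resolutions$visit_id) {
      out$status[i] <- "consensus_resolved"
      out$om_considered[i] <- as.logical(
        resolutions$om_considered[resolutions$visit_id == ids[i]])
    } else {
      out$status[i] <- "unresolved"
    }
  }
  out
}

snippet_around <- function(text, start, end, radius) {
  lo <- max(1L, start - radius)
  hi <- min(nchar(text), end + radius)
  paste0(if (lo > 1L) "..." else "", substr(text, lo, hi),
         if (hi < nchar(text)) "..." else "")
}

#' Report algorithm/clinician discrepancies
#'
#' One row per false-positive (flagged but gold-negative) and
#' false-negative (unflagged but gold-positive) visit, false positives
#' first, each group sorted by visit_id. Each row carries the matched term
#' surfaces and a text snippet around each match (default 40 characters of
#' context per side); false negatives, which may have no match at all, get
#' the leading snippet of the note. Counts always reconcile with
#' [build_confusion()] on the same inputs.
#'
#' @param results an `om_screen_set` (or visit_id/flagged data.frame; then
#'   match provenance columns are empty).
#' @param gold gold-label data.frame (visit_id, om_considered).
#' @param records the screened corpus data.frame.
#' @param radius snippet context radius in characters (default 40).
#' @return data.frame with columns visit_id, kind
#'   (false_positive/false_negative), terms, snippet.
#' @export
discrepancy_report <- function(results, gold, records, radius = 40L) {
  flags <- if (inherits(results, "om_screen_set")) results$flags else results
  orphans <- c(setdiff(flags$visit_id, records$visit_id),
               setdiff(gold$visit_id, records$visit_id))
  if (length(orphans)) {
    stop("ids not present in corpus: ",
         paste(sQuote(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  cm_check <- build_confusion(flags, gold)  # also validates id alignment

  g <- gold$om_considered[match(flags$visit_id, gold$visit_id)]
  fp_ids <- sort(flags$visit_id[flags$flagged & !g])
  fn_ids <- sort(flags$visit_id[!flags$flagged & g])

  describe <- function(vid, kind) {
    text <- records$text[records$visit_id == vid]
    m <- NULL
    if (inherits(results, "om_screen_set")) {
      r <- results$results[[match(vid, flags$visit_id)]]
      m <- if (kind == "false_positive") {
        r$matches[!r$matches$excluded, , drop = FALSE]
      } else r$matches
    }
    if (!is.null(m) && nrow(m)) {
      terms <- paste(m$surface, collapse = "; ")
      snips <- vapply(seq_len(nrow(m)), function(i)
        snippet_around(text, m$start[i], m$end[i], radius), character(1))
      snippet <- paste(unique(snips), collapse = " | ")
    } else {
      terms <- ""
      snippet <- snippet_around(text, 1L, min(nchar(text), 1L), radius)
    }
    data.frame(visit_id = vid, kind = kind, terms = terms,
               snippet = snippet, stringsAsFactors = FALSE)
  }
  rows <- c(lapply(fp_ids, describe, kind = "false_positive"),
            lapply(fn_ids, describe, kind = "false_negative"))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(visit_id = character(0), kind = character(0),
               terms = character(0), snippet = character(0),
               stringsAsFactors = FALSE)
  stopifnot(sum(out$kind == "false_positive") == cm_check$fp,
            sum(out$kind == "false_negative") == cm_check$fn)
  out
}

#' Suggest exclusion-word candidates from false positives
#'
#' Tooling beyond the original validation: automates the human step of
#' scanning false-positive visits for words that could be added to the
#' exclusion list. Candidate words are tokens co-occurring (within the
#' active combination-policy scope) with retained matches in false-positive
#' visits, ranked by the number of FP visits they would touch
#' (`fp_support`, descending) with the number of true-positive visits they
#' would also touch (`flagged_tp_support`, ascending) as penalty
#' tie-breaker. Existing lexicon entries are never suggested.
#'
#' @param fp_discrepancies the false_positive rows of
#'   [discrepancy_report()] (rows of other kinds are ignored).
#' @param records the corpus the discrepancies came from.
#' @param lx the active lexicon.
#' @param top_k maximum number of suggestions.
#' @param gold optional gold labels; when supplied, true-positive visits
#'   are taken from them, otherwise every flagged non-FP visit counts as a
#'   TP for the penalty.
#' @return data.frame with columns word, fp_support, flagged_tp_support,
#'   at most `top_k` rows.
#' @export
suggest_exclusion_candidates <- function(fp_discrepancies, records, lx,
                                         top_k = 10L, gold = NULL) {
  validate_lexicon(lx)
  fp_ids <- unique(fp_discrepancies$visit_id[
    fp_discrepancies$kind == "false_positive"])
  empty <- data.frame(word = character(0), fp_support = integer(0),
                      flagged_tp_support = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(fp_ids)) return(empty)

  screen <- screen_corpus(records, lx)
  flagged_ids <- screen$flags$visit_id[screen$flags$flagged]
  tp_ids <- if (!is.null(gold)) {
    intersect(flagged_ids,
              gold$visit_id[as.logical(gold$om_considered)])
  } else setdiff(flagged_ids, fp_ids)

  known <- tolower(c(lx$search_terms$surface, lx$exclusion_words$surface))
  neighbour_words <- function(vid) {
    text <- records$text[records$visit_id == vid]
    r <- screen$results[[match(vid, screen$flags$visit_id)]]
    m <- r$matches[!r$matches$excluded, , drop = FALSE]
    if (!nrow(m)) return(character(0))
    tokens <- tokenize_text(text)
    if (!nrow(tokens)) return(character(0))
    sids <- if (lx$policy$mode == "sentence") sentence_ids(text) else NULL
    words <- character(0)
    for (i in seq_len(nrow(m))) {
      m_tok <- token_range(tokens, m$start[i], m$end[i])
      for (t in seq_len(nrow(tokens))) {
        if (t >= m_tok[1] && t <= m_tok[2]) next
        if (scope_qualifies(lx$policy, m_tok, m$start[i], m$end[i],
                            c(t, t), tokens$start[t], tokens$end[t], sids)) {
          words <- c(words, tolower(tokens$token[t]))
        }
      }
    }
    unique(words)
  }
  fp_words <- lapply(fp_ids, neighbour_words)
  tp_words <- lapply(tp_ids, neighbour_words)
  vocab <- setdiff(unique(unlist(fp_words)), known)
  if (!length(vocab)) return(empty)
  fp_support <- vapply(vocab, function(w)
    sum(vapply(fp_words, function(ws) w %in% ws, logical(1))), integer(1))
  tp_support <- vapply(vocab, function(w)
    sum(vapply(tp_words, function(ws) w %in% ws, logical(1))), integer(1))
  out <- data.frame(word = vocab, fp_support = fp_support,
                    flagged_tp_support = tp_support,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fp_support, out$flagged_tp_support, out$word), ,
             drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Export a clinician-review worksheet
#'
#' One CSV row per flagged visit (visit_id, child_id, visit_date, matched
#' term surfaces, snippets, and empty `reviewer_label`/`notes` columns),
#' ordered by child then date, ready for the final manual-review pass. The
#' row count always equals tp + fp of the eventual confusion matrix.
#'
#' @param results an `om_screen_set`.
#' @param records the screened corpus.
#' @param path output CSV path.
#' @param radius snippet radius (default 40).
#' @return `path`, invisibly.
#' @export
export_review_worksheet <- function(results, records, path, radius = 40L) {
  stopifnot(inherits(results, "om_screen_set"))
  orphan <- setdiff(results$flags$visit_id, records$visit_id)
  if (length(orphan)) {
    stop("flagged results reference unknown records: ",
         paste(sQuote(orphan), collapse = ", "), call. = FALSE)
  }
  flagged <- Filter(function(r) r$flagged, results$results)
  rows <- lapply(flagged, function(r) {
    rec <- records[records$visit_id == r$visit_id, , drop = FALSE]
    m <- r$matches[!r$matches$excluded, , drop = FALSE]
    snips <- vapply(seq_len(nrow(m)), function(i)
      snippet_around(rec$text, m$start[i], m$end[i], radius), character(1))
    data.frame(
      visit_id = r$visit_id, child_id = rec$child_id,
      visit_date = rec$visit_date %||% NA_character_,
      matched_terms = paste(m$surface, collapse = "; "),
      snippets = paste(unique(snips), collapse = " | "),
      reviewer_label = "", notes = "",
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(visit_id = character(0), child_id = character(0),
               visit_date = character(0), matched_terms = character(0),
               snippets = character(0), reviewer_label = character(0),
               notes = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$child_id, out$visit_date, out$visit_id), ,
             drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
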
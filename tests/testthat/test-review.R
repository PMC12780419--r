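reviewer_labels <- function(visits, votes_by_reviewer) {
  do.call(rbind, lapply(seq_along(votes_by_reviewer), function(r) {
    data.frame(visit_id = visits, reviewer_id = paste0("r", r),
               om_considered = votes_by_reviewer[[r]],
               stringsAsFactors = FALSE)
  }))
}

test_that("adjudicate: unanimity, explicit consensus, no majority vote", {
  labels <- reviewer_labels(c("a", "b", "c"), list(
    c(TRUE, TRUE, FALSE),
    c(TRUE, FALSE, FALSE),
    c(TRUE, TRUE, FALSE)))
  # a: unanimous TRUE; b: 2v1 discordant; c: unanimous FALSE
  out <- adjudicate(labels)
  expect_equal(out$status, c("unanimous", "unresolved", "unanimous"))
  expect_equal(out$om_considered, c(TRUE, NA, FALSE))

  # a supplied resolution settles the discordant visit only
  res <- data.frame(visit_id = "b", om_considered = TRUE)
  out2 <- adjudicate(labels, res)
  expect_equal(out2$status[out2$visit_id == "b"], "consensus_resolved")
  expect_true(out2$om_considered[out2$visit_id == "b"])
  # adjudication never contradicts a unanimous input
  expect_equal(out2$om_considered[out2$visit_id == "a"], TRUE)

  # resolution for a unanimous visit is an error
  expect_error(adjudicate(labels,
                          data.frame(visit_id = "a", om_considered = FALSE)),
               "unanimous")
  # duplicate resolution is an error
  expect_error(adjudicate(labels, rbind(res, res)), "duplicate resolution")
  # fewer than two reviewers is an error
  one <- labels[labels$reviewer_id == "r1", ]
  expect_error(adjudicate(one), ">= 2 reviewers")

  # exhaustive 2-reviewer agreement patterns
  for (v1 in c(TRUE, FALSE)) for (v2 in c(TRUE, FALSE)) {
    o <- adjudicate(reviewer_labels("x", list(v1, v2)))
    if (v1 == v2) {
      expect_equal(o$status, "unanimous")
      expect_equal(o$om_considered, v1)
    } else {
      expect_equal(o$status, "unresolved")
      expect_true(is.na(o$om_considered))
    }
  }
})

test_that("discrepancy_report reconciles with the confusion matrix", {
  lx <- test_lexicon()
  records <- data.frame(
    child_id = c("c1", "c1", "c2", "c2", "c3"),
    visit_id = c("v1", "v2", "v3", "v4", "v5"),
    visit_date = NA_character_,
    text = c("AOM right side",                    # TP
             "ROM improving since physio",        # FP (ambiguous abbrev)
             "well child visit",                  # TN
             "brother has otitis media",          # FP (family mention)
             "ear discharge noted"),              # FN (no term present)
    stringsAsFactors = FALSE)
  gold <- data.frame(
    visit_id = paste0("v", 1:5),
    om_considered = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  screen <- screen_corpus(records, lx)
  rep <- discrepancy_report(screen, gold, records)
  cm <- build_confusion(screen, gold)
  expect_equal(sum(rep$kind == "false_positive"), cm$fp)
  expect_equal(sum(rep$kind == "false_negative"), cm$fn)
  # FPs first, then by visit_id
  expect_equal(rep$kind, c("false_positive", "false_positive",
                           "false_negative"))
  expect_equal(rep$visit_id, c("v2", "v4", "v5"))
  # the ambiguous-ROM FP's snippet contains the match
  expect_match(rep$snippet[rep$visit_id == "v2"], "ROM")

  # perfect agreement -> empty report
  perfect_gold <- data.frame(visit_id = paste0("v", 1:5),
                             om_considered = screen$flags$flagged)
  expect_equal(nrow(discrepancy_report(screen, perfect_gold, records)), 0L)

  # orphan ids are listed
  expect_error(discrepancy_report(screen, gold, records[-1, ]),
               "not present.*v1")
})

test_that("suggest_exclusion_candidates ranks planted decoys first", {
  lx <- test_lexicon()
  # decoy 'resolving' co-occurs with the term in all FP visits, never in TPs
  records <- data.frame(
    child_id = "c", visit_id = sprintf("v%d", 1:8),
    visit_date = NA_character_,
    text = c(sprintf("tm resolving %s", c("alpha", "beta", "gamma",
                                          "delta", "epsilon")),  # FPs
             "AOM diagnosed today",                        # TP
             "otitis media confirmed",                     # TP
             "routine immunisation"),                      # TN
    stringsAsFactors = FALSE)
  gold <- data.frame(visit_id = sprintf("v%d", 1:8),
                     om_considered = c(rep(FALSE, 5), TRUE, TRUE, FALSE))
  screen <- screen_corpus(records, lx)
  rep <- discrepancy_report(screen, gold, records)
  sugg <- suggest_exclusion_candidates(rep, records, lx, top_k = 3,
                                       gold = gold)
  expect_equal(sugg$word[1], "resolving")
  expect_equal(sugg$fp_support[1], 5L)
  expect_equal(sugg$flagged_tp_support[1], 0L)
  # never suggests existing lexicon entries
  expect_false(any(tolower(c(lx$search_terms$surface,
                             lx$exclusion_words$surface)) %in% sugg$word))
  # empty FP set -> empty suggestions
  empty <- suggest_exclusion_candidates(rep[0, ], records, lx)
  expect_equal(nrow(empty), 0L)

  # adding the top suggestion never increases the FP count (monotonicity)
  lx2 <- lexicon(lx$search_terms,
                 rbind(lx$exclusion_words,
                       data.frame(surface = sugg$word[1],
                                  case_sensitive = FALSE)),
                 policy = lx$policy, version = "refined")
  cm_before <- build_confusion(screen, gold)
  cm_after <- build_confusion(screen_corpus(records, lx2), gold)
  expect_lte(cm_after$fp, cm_before$fp)
})

test_that("export_review_worksheet lists exactly the flagged visits", {
  lx <- test_lexicon()
  records <- data.frame(
    child_id = c("c2", "c1", "c1"),
    visit_id = c("v1", "v2", "v3"),
    visit_date = c("2013-05-01", "2013-02-01", "2013-01-01"),
    text = c("AOM left", "tm normal today", "otitis media likely"),
    stringsAsFactors = FALSE)
  screen <- screen_corpus(records, lx)
  path <- withr::local_tempfile(fileext = ".csv")
  export_review_worksheet(screen, records, path)
  ws <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(ws), sum(screen$flags$flagged))
  # ordered by child then date
  expect_equal(ws$visit_id, c("v3", "v1"))
  expect_true(all(c("reviewer_label", "notes") %in% names(ws)))
  expect_match(ws$matched_terms[ws$visit_id == "v1"], "AOM")

  # row count equals tp+fp of the eventual confusion matrix
  gold <- data.frame(visit_id = paste0("v", 1:3),
                     om_considered = c(TRUE, FALSE, FALSE))
  cm <- build_confusion(screen, gold)
  expect_equal(nrow(ws), cm$tp + cm$fp)

  # zero flagged -> header-only file
  none <- screen_corpus(records[2, , drop = FALSE], lx)
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_review_worksheet(none, records, path2)
  expect_equal(nrow(read.csv(path2)), 0L)
})
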
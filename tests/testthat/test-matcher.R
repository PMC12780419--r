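test_that("find_term_occurrences respects word boundaries and case rules", {
  lx <- test_lexicon()

  # the documented family-mention phrase matches at the phrase span
  m <- find_term_occurrences("brother has otitis media", lx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "otitis media")
  expect_equal(substr("brother has otitis media", m$start, m$end),
               "otitis media")

  # empty text and absent terms
  expect_equal(nrow(find_term_occurrences("", lx)), 0L)
  expect_equal(nrow(find_term_occurrences("no ear words here at all", lx)),
               0L)

  # 'tm' inside "treatment" fails the boundary rule
  expect_equal(nrow(find_term_occurrences("treatment given", lx)), 0L)
  # but stands alone, at line boundaries, and next to punctuation
  expect_equal(find_term_occurrences("tm", lx)$surface, "tm")
  expect_equal(nrow(find_term_occurrences("red tm, bulging", lx)), 1L)
  expect_equal(nrow(find_term_occurrences("x\ntm\ny", lx)), 1L)

  # case sensitivity: 'TM' does not match 'Tm'; 'otitis media' matches
  # any casing
  expect_equal(nrow(find_term_occurrences("Tm looks odd", lx)), 0L)
  expect_equal(nrow(find_term_occurrences("Otitis Media suspected", lx)),
               1L)

  # slash inside a term is literal; T/M is found as one unit
  m2 <- find_term_occurrences("L T/M bulging", lx)
  expect_equal(m2$surface, "T/M")

  # overlapping occurrences of different terms are all reported
  m3 <- find_term_occurrences("ear infection", lx)
  expect_true("ear infection" %in% m3$surface)

  # ordering by (start, end)
  m4 <- find_term_occurrences("OM then tm then AOM", lx)
  expect_equal(m4$start, sort(m4$start))
})

test_that("apply_exclusion_rules implements the combination policy per match", {
  lx <- test_lexicon()  # window 3, bidirectional

  # "tm normal": excluded, provenance records the exclusion word
  r <- screen_visit(list(visit_id = "v", text = "tm normal"), lx)
  expect_false(r$flagged)
  expect_true(r$matches$excluded)
  expect_equal(r$matches$excl_surface, "normal")
  expect_equal(substr("tm normal", r$matches$excl_start,
                      r$matches$excl_end), "normal")

  # per-match exclusion: the negated TM does not suppress the AOM
  r2 <- screen_visit(list(visit_id = "v",
                          text = "TM normal but L ear AOM"), lx)
  expect_true(r2$flagged)
  expect_equal(r2$matches$excluded[r2$matches$surface == "TM"], TRUE)
  expect_equal(r2$matches$excluded[r2$matches$surface == "AOM"], FALSE)

  # bidirectionality: "normal TM" excluded when on, retained when off
  expect_false(screen_visit(list(visit_id = "v", text = "normal TM"),
                            lx)$flagged)
  lx_uni <- test_lexicon(bidirectional = FALSE)
  expect_true(screen_visit(list(visit_id = "v", text = "normal TM"),
                           lx_uni)$flagged)

  # window limit: 3 intervening tokens is out of reach in phrase mode
  lx_phrase <- test_lexicon(mode = "phrase")
  expect_false(screen_visit(list(visit_id = "v", text = "tm looks normal"),
                            lx)$flagged)       # dist 2 <= window 3
  expect_true(screen_visit(list(visit_id = "v", text = "tm looks normal"),
                           lx_phrase)$flagged) # dist 2 > adjacent

  # sentence scope stops at the boundary; record scope does not
  txt <- "tm red. everything else normal"
  lx_sent <- test_lexicon(mode = "sentence")
  lx_rec <- test_lexicon(mode = "record")
  expect_true(screen_visit(list(visit_id = "v", text = txt),
                           lx_sent)$flagged)
  expect_false(screen_visit(list(visit_id = "v", text = txt),
                            lx_rec)$flagged)

  # nearest qualifying exclusion wins, earlier offset on ties:
  # "clear tm normal" has a 1-char gap on both sides -> earlier offset
  lx_rec2 <- test_lexicon(mode = "record")
  r3 <- screen_visit(list(visit_id = "v", text = "clear tm normal"), lx_rec2)
  expect_equal(r3$matches$excl_surface, "clear")
  # widen the left gap and 'normal' becomes strictly nearer
  r4 <- screen_visit(list(visit_id = "v", text = "clear  tm normal"),
                     lx_rec2)
  expect_equal(r4$matches$excl_surface, "normal")

  # no exclusion words -> unchanged
  lx_none <- lexicon(test_lexicon()$search_terms)
  m <- find_term_occurrences("tm normal", lx_none)
  expect_identical(apply_exclusion_rules("tm normal", m, lx_none), m)

  # integrity: spans must reproduce the surface
  mbad <- find_term_occurrences("tm normal", lx)
  mbad$start <- mbad$start + 1L
  expect_error(apply_exclusion_rules("tm normal", mbad, lx), "integrity")
})

test_that("known contextual false positives are flagged by design", {
  lx <- test_lexicon()
  # family mention
  expect_true(screen_visit(list(visit_id = "v",
                                text = "brother has otitis media"),
                           lx)$flagged)
  # ambiguous abbreviation: ROM as range of movement
  expect_true(screen_visit(list(visit_id = "v",
                                text = "ROM improving since physio"),
                           lx)$flagged)
  # empty note
  r <- screen_visit(list(visit_id = "v", text = ""), lx)
  expect_false(r$flagged)
  expect_equal(nrow(r$matches), 0L)
})

test_that("screen_corpus preserves order, rejects duplicates, audits exclusions", {
  lx <- test_lexicon()
  records <- data.frame(
    child_id = "c1", visit_id = c("a", "b", "c"),
    visit_date = NA_character_,
    text = c("well child", "otitis media suspected", "tm normal"),
    stringsAsFactors = FALSE)
  s <- screen_corpus(records, lx)
  expect_equal(s$flags$visit_id, c("a", "b", "c"))
  expect_equal(s$flags$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(s$audit$visit_id, "c")
  expect_equal(s$audit$excl_surface, "normal")

  dup <- records
  dup$visit_id <- c("a", "a", "c")
  expect_error(screen_corpus(dup, lx), "duplicate visit_id")

  # determinism
  expect_identical(screen_corpus(records, lx), s)
})

test_that("matcher equals the brute-force oracle on random text (all modes)", {
  set.seed(11)
  for (mode in c("phrase", "window", "sentence", "record")) {
    for (bidir in c(TRUE, FALSE)) {
      lx <- test_lexicon(mode = mode, window_tokens = 2L,
                         bidirectional = bidir)
      for (rep in 1:40) {
        txt <- random_text()
        got <- screen_visit(list(visit_id = "v", text = txt), lx)$matches
        got_retained <- got[!got$excluded, , drop = FALSE]
        want <- oracle_retained(txt, lx)
        expect_equal(
          sort(paste(got_retained$surface, got_retained$start,
                     got_retained$end)),
          sort(paste(want$surface, want$start, want$end)),
          info = sprintf("mode=%s bidir=%s text=%s", mode, bidir,
                         encodeString(txt)))
      }
    }
  }
})

test_that("tokenizer matches its independent oracle", {
  set.seed(12)
  for (rep in 1:50) {
    txt <- random_text()
    got <- tokenize_text(txt)
    want <- oracle_tokens(txt)
    expect_equal(got$start, want$start, info = encodeString(txt))
    expect_equal(got$end, want$end, info = encodeString(txt))
  }
  expect_equal(tokenize_text("T/M red")$token, c("T/M", "red"))
  expect_equal(tokenize_text("a//b")$token, c("a", "b"))
  expect_equal(nrow(tokenize_text("...")), 0L)
})
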
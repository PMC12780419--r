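# Independent brute-force oracles. Deliberately written as plain loops over
# character positions and (match, exclusion-occurrence) pairs, sharing no
# code with the package implementation.

oracle_is_alnum <- function(ch) {
  nzchar(ch) && grepl("^[0-9A-Za-z]$", ch)
}

# every boundary-respecting occurrence of every term, by exhaustive
# enumeration of substring positions
oracle_locate <- function(text, surfaces, case_sensitive) {
  n <- nchar(text)
  out <- list()
  for (k in seq_along(surfaces)) {
    surf <- surfaces[k]
    L <- nchar(surf)
    if (L > n) next
    cmp_surf <- if (case_sensitive[k]) surf else tolower(surf)
    starts <- seq_len(n - L + 1L)
    subs <- substring(text, starts, starts + L - 1L)
    if (!case_sensitive[k]) subs <- tolower(subs)
    for (s in starts[subs == cmp_surf]) {
      e <- s + L - 1L
      before_ok <- s == 1L || !oracle_is_alnum(substr(text, s - 1L, s - 1L))
      after_ok <- e == n || !oracle_is_alnum(substr(text, e + 1L, e + 1L))
      if (before_ok && after_ok) {
        out[[length(out) + 1L]] <- data.frame(
          surface = surf, start = s, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[!duplicated(paste(df$surface, df$start)), , drop = FALSE]
  df <- df[order(df$start, df$end, df$surface), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# character-by-character tokenizer: alnum runs, '/' joins two alnum runs
oracle_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (oracle_is_alnum(chars[i])) {
      j <- i
      repeat {
        while (j < n && oracle_is_alnum(chars[j + 1L])) j <- j + 1L
        if (j + 2L <= n && chars[j + 1L] == "/" &&
            oracle_is_alnum(chars[j + 2L])) {
          j <- j + 2L
        } else break
      }
      spans[[length(spans) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(spans)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, spans)
  data.frame(start = m[, 1], end = m[, 2])
}

oracle_sentence_of <- function(text, pos) {
  if (pos <= 1L) return(1L)
  prefix <- strsplit(substr(text, 1L, pos - 1L), "", fixed = TRUE)[[1]]
  1L + sum(prefix %in% c(".", "!", "?", "\n"))
}

# does exclusion occurrence (es, ee) suppress match (ms, me) under policy?
oracle_in_scope <- function(text, ms, me, es, ee, policy) {
  if (policy$mode == "record") return(TRUE)
  if (policy$mode == "sentence") {
    return(oracle_sentence_of(text, ms) == oracle_sentence_of(text, es))
  }
  toks <- oracle_tokens(text)
  mtok <- which(toks$start <= me & toks$end >= ms)
  etok <- which(toks$start <= ee & toks$end >= es)
  if (!length(mtok) || !length(etok)) return(FALSE)
  if (min(etok) > max(mtok)) {
    dist <- min(etok) - max(mtok)
  } else if (max(etok) < min(mtok)) {
    if (!policy$bidirectional) return(FALSE)
    dist <- min(mtok) - max(etok)
  } else dist <- 0L
  lim <- if (policy$mode == "phrase") 1L else policy$window_tokens
  dist <= lim
}

# retained (non-excluded) matches by exhaustive pair enumeration
oracle_retained <- function(text, lx) {
  m <- oracle_locate(text, lx$search_terms$surface,
                     lx$search_terms$case_sensitive)
  if (!nrow(m) || !nrow(lx$exclusion_words)) return(m)
  ex <- oracle_locate(text, lx$exclusion_words$surface,
                      lx$exclusion_words$case_sensitive)
  if (!nrow(ex)) return(m)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    excluded <- FALSE
    for (j in seq_len(nrow(ex))) {
      if (oracle_in_scope(text, m$start[i], m$end[i],
                          ex$start[j], ex$end[j], lx$policy)) {
        excluded <- TRUE
        break
      }
    }
    keep[i] <- !excluded
  }
  m[keep, , drop = FALSE]
}

oracle_flagged <- function(text, lx) nrow(oracle_retained(text, lx)) > 0L

# Clopper-Pearson by bisection on the binomial tail probabilities
oracle_cp_interval <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    # 120 halvings of (0,1) put the bracket width far below the comparison
    # tolerance even relative to very small bounds
    for (it in 1:120) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
           0, 1)
  upper <- if (k == n) 1 else
    bisect(function(p) alpha / 2 - pbinom(k, n, p), 0, 1)
  c(lower = lower, upper = upper)
}

# ---- fixtures ---------------------------------------------------------

test_lexicon <- function(mode = "window", window_tokens = 3L,
                         bidirectional = TRUE) {
  lexicon(
    search_terms = data.frame(
      surface = c("otitis media", "OM", "AOM", "ROM", "T/M", "tm", "TM",
                  "ear infection"),
      case_sensitive = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE
    ),
    exclusion_words = data.frame(
      surface = c("normal", "clear", "NAD"),
      case_sensitive = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    ),
    policy = combination_policy(mode = mode, window_tokens = window_tokens,
                                bidirectional = bidirectional),
    version = "test"
  )
}

# random note-like text over a vocabulary of terms, exclusion words,
# prefix-sharing decoys and boundary punctuation
random_text <- function(max_pieces = 60L) {
  vocab <- c("otitis media", "OM", "AOM", "ROM", "T/M", "tm", "TM",
             "ear infection", "normal", "clear", "NAD",
             "treatment", "atm", "ROMs", "OMG", "tms", "normally",
             "clearance", "nad", "otitis", "media", "ear", "infections",
             "Tm", "om", "aom", "t/m", "drum", "red", "L", "R", "bil")
  seps <- c(" ", " ", " ", ", ", ". ", "! ", "? ", "\n", "-", "/", " (", ") ")
  n <- sample.int(max_pieces, 1L)
  pieces <- sample(vocab, n, replace = TRUE)
  joins <- sample(seps, n, replace = TRUE)
  out <- paste0(paste0(pieces, joins[seq_len(n)]), collapse = "")
  substr(out, 1L, 500L)
}

demo_path <- function(f) system.file("extdata", f, package = "omscreen")
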
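#' Construct a screening lexicon
#'
#' A lexicon is the complete rule set of the screening algorithm: an ordered
#' list of search terms whose presence suggests otitis media (OM) was
#' considered during a visit, an ordered list of exclusion words that negate
#' a search term when the two co-occur, and a combination policy defining
#' the textual scope within which an exclusion word applies to a found term.
#'
#' Exclusion words form a single global list applied to every search term:
#' each found term is compared against all exclusion words, and the nearest
#' qualifying exclusion occurrence (by character distance, earlier offset on
#' ties) is recorded as the reason the match was suppressed.
#'
#' @param search_terms data.frame with columns `surface` (character),
#'   `case_sensitive` (logical) and optionally `note` (character provenance).
#' @param exclusion_words data.frame with columns `surface` and
#'   `case_sensitive`. May have zero rows, in which case the exclusion stage
#'   is a no-op.
#' @param policy a policy list from [combination_policy()].
#' @param version character version label.
#' @return An object of class `om_lexicon`.
#' @seealso [load_lexicon()], [save_lexicon()], [merge_lexicons()],
#'   [seed_lexicon()]
#' @export
lexicon <- function(search_terms,
                    exclusion_words = empty_exclusions(),
                    policy = combination_policy(),
                    version = "unversioned") {
  search_terms <- normalize_term_frame(search_terms, need_note = TRUE)
  exclusion_words <- normalize_term_frame(exclusion_words, need_note = FALSE)
  lx <- structure(
    list(
      search_terms = search_terms,
      exclusion_words = exclusion_words,
      policy = policy,
      version = as.character(version)[1]
    ),
    class = "om_lexicon"
  )
  validate_lexicon(lx)
  lx
}

#' Combination policy for exclusion-word matching
#'
#' Defines how close an exclusion word must be to a found search term for
#' the term to be suppressed ("OM excluded"):
#' \describe{
#'   \item{phrase}{the exclusion word is the immediately adjacent token
#'     ("TM normal").}
#'   \item{window}{the exclusion word lies within `window_tokens` tokens of
#'     the term ("TM looks normal"). The default.}
#'   \item{sentence}{same sentence, where sentences end at `.`, `!`, `?`
#'     or a newline.}
#'   \item{record}{anywhere in the visit text.}
#' }
#'
#' @param mode one of "phrase", "window", "sentence", "record".
#' @param window_tokens positive integer; maximum token distance in window
#'   mode (default 3).
#' @param bidirectional logical; whether an exclusion word *before* the
#'   search term also triggers exclusion in phrase/window modes (sentence
#'   and record modes are inherently bidirectional). Default TRUE, so that
#'   both "TM normal" and "normal TM" are suppressed.
#' @return A list of class `om_policy`.
#' @export
combination_policy <- function(mode = c("window", "phrase", "sentence", "record"),
                               window_tokens = 3L,
                               bidirectional = TRUE) {
  mode <- match.arg(mode)
  window_tokens <- as.integer(window_tokens)
  if (is.na(window_tokens) || window_tokens < 1L) {
    stop("policy: window_tokens must be a positive integer", call. = FALSE)
  }
  stopifnot(is.logical(bidirectional), length(bidirectional) == 1L,
            !is.na(bidirectional))
  structure(
    list(mode = mode, window_tokens = window_tokens,
         bidirectional = bidirectional),
    class = "om_policy"
  )
}

empty_exclusions <- function() {
  data.frame(surface = character(0), case_sensitive = logical(0),
             stringsAsFactors = FALSE)
}

# Coerce a term table to canonical column types; trim nothing silently --
# leading/trailing whitespace is an invariant violation, caught by the
# validator so that data-file errors surface loudly.
normalize_term_frame <- function(df, need_note) {
  if (!is.data.frame(df)) stop("terms must be a data.frame", call. = FALSE)
  if (!all(c("surface", "case_sensitive") %in% names(df))) {
    stop("term table needs columns 'surface' and 'case_sensitive'",
         call. = FALSE)
  }
  out <- data.frame(
    surface = as.character(df$surface),
    case_sensitive = as.logical(df$case_sensitive),
    stringsAsFactors = FALSE
  )
  if (need_note) {
    out$note <- if ("note" %in% names(df)) as.character(df$note) else
      rep(NA_character_, nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Validate a lexicon against its invariants
#'
#' Checks: at least one search term; all surfaces non-empty and free of
#' leading/trailing whitespace; no duplicate (surface, case_sensitive) pair
#' within either list; no search term equal to an exclusion word under the
#' term's own case rule (a term cannot exclude itself); well-formed policy.
#'
#' @param lx an `om_lexicon`.
#' @return `lx`, invisibly. Errors describe every violation found.
#' @export
validate_lexicon <- function(lx) {
  stopifnot(inherits(lx, "om_lexicon"))
  problems <- character(0)
  st <- lx$search_terms
  ex <- lx$exclusion_words

  if (nrow(st) == 0L) problems <- c(problems, "no search terms defined")

  check_surfaces <- function(df, label) {
    bad <- character(0)
    if (any(is.na(df$surface) | df$surface == "")) {
      bad <- c(bad, sprintf("%s: empty surface", label))
    }
    untrimmed <- df$surface[!is.na(df$surface) &
                              df$surface != trimws(df$surface)]
    if (length(untrimmed)) {
      bad <- c(bad, sprintf("%s: leading/trailing whitespace in %s", label,
                            paste(sQuote(untrimmed), collapse = ", ")))
    }
    if (any(is.na(df$case_sensitive))) {
      bad <- c(bad, sprintf("%s: missing case_sensitive flag", label))
    }
    key <- paste(df$surface, df$case_sensitive, sep = "\r")
    dup <- unique(df$surface[duplicated(key)])
    if (length(dup)) {
      bad <- c(bad, sprintf("%s: duplicate entries %s", label,
                            paste(sQuote(dup), collapse = ", ")))
    }
    bad
  }
  problems <- c(problems, check_surfaces(st, "search_terms"))
  problems <- c(problems, check_surfaces(ex, "exclusion_words"))

  # a term must never be its own exclusion word
  if (nrow(st) && nrow(ex)) {
    for (i in seq_len(nrow(st))) {
      hit <- if (st$case_sensitive[i]) {
        st$surface[i] %in% ex$surface
      } else {
        tolower(st$surface[i]) %in% tolower(ex$surface)
      }
      if (isTRUE(hit)) {
        problems <- c(problems, sprintf(
          "search term %s also appears as an exclusion word",
          sQuote(st$surface[i])))
      }
    }
  }

  if (!inherits(lx$policy, "om_policy")) {
    problems <- c(problems, "policy is not a combination_policy()")
  }

  if (length(problems)) {
    stop("invalid lexicon:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(lx)
}

#' @export
print.om_lexicon <- function(x, ...) {
  cat(sprintf("<om_lexicon> version '%s'\n", x$version))
  cat(sprintf("  %d search terms, %d exclusion words\n",
              nrow(x$search_terms), nrow(x$exclusion_words)))
  cat(sprintf("  policy: %s (window_tokens=%d, bidirectional=%s)\n",
              x$policy$mode, x$policy$window_tokens, x$policy$bidirectional))
  invisible(x)
}

#' @export
print.om_policy <- function(x, ...) {
  cat(sprintf("<om_policy> mode=%s window_tokens=%d bidirectional=%s\n",
              x$mode, x$window_tokens, x$bidirectional))
  invisible(x)
}

#' Load a lexicon from YAML or CSV
#'
#' YAML schema: top-level keys `version`, `policy`
#' (`{mode, window_tokens, bidirectional}`), `search_terms` (list of
#' `{surface, case_sensitive, note}`) and `exclusion_words` (list of
#' `{surface, case_sensitive}`). CSV dialect: columns
#' `kind` (`search`/`exclusion`), `surface`, `case_sensitive`, `note`; the
#' policy is not representable in the CSV rows and is supplied via the
#' `policy` argument (defaulting to [combination_policy()]).
#'
#' Ordering of terms is preserved from the file. The returned lexicon is
#' fully validated.
#'
#' @param path file path.
#' @param format "yaml" or "csv"; default inferred from the file extension.
#' @param policy combination policy used for csv input (ignored for yaml,
#'   which carries its own).
#' @return A validated `om_lexicon`.
#' @export
load_lexicon <- function(path, format = c("auto", "yaml", "csv"),
                         policy = combination_policy()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     yaml = , yml = "yaml",
                     csv = "csv",
                     stop("cannot infer lexicon format from ", sQuote(path),
                          "; pass format=", call. = FALSE))
  }
  if (!file.exists(path)) {
    stop("lexicon file not found: ", sQuote(path), call. = FALSE)
  }
  if (format == "yaml") {
    doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("lexicon YAML parse failure in ", sQuote(path), ": ",
           conditionMessage(e), call. = FALSE)
    })
    need <- c("version", "policy", "search_terms")
    missing <- setdiff(need, names(doc))
    if (length(missing)) {
      stop("lexicon YAML missing field(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    terms_to_df <- function(lst, need_note) {
      if (is.null(lst) || length(lst) == 0L) return(empty_exclusions())
      df <- data.frame(
        surface = vapply(lst, function(e) as.character(e$surface %||% NA),
                         character(1)),
        case_sensitive = vapply(lst, function(e)
          as.logical(e$case_sensitive %||% NA), logical(1)),
        stringsAsFactors = FALSE
      )
      if (need_note) {
        df$note <- vapply(lst, function(e)
          as.character(e$note %||% NA_character_), character(1))
      }
      df
    }
    pol <- doc$policy
    lexicon(
      search_terms = terms_to_df(doc$search_terms, need_note = TRUE),
      exclusion_words = terms_to_df(doc$exclusion_words, need_note = FALSE),
      policy = combination_policy(
        mode = pol$mode %||% "window",
        window_tokens = pol$window_tokens %||% 3L,
        bidirectional = pol$bidirectional %||% TRUE
      ),
      version = doc$version
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("kind", "surface", "case_sensitive")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("lexicon CSV ", sQuote(path), " missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    badkind <- setdiff(unique(df$kind), c("search", "exclusion"))
    if (length(badkind)) {
      stop("lexicon CSV: unknown kind value(s) ",
           paste(sQuote(badkind), collapse = ", "), call. = FALSE)
    }
    df$case_sensitive <- parse_logical(df$case_sensitive, "case_sensitive")
    if (!"note" %in% names(df)) df$note <- NA_character_
    df$note[!is.na(df$note) & df$note == ""] <- NA_character_
    st <- df[df$kind == "search", c("surface", "case_sensitive", "note")]
    ex <- df[df$kind == "exclusion", c("surface", "case_sensitive")]
    lexicon(st, ex, policy = policy,
            version = attr(df, "version") %||% "csv-import")
  }
}

#' Save a lexicon to YAML or CSV
#'
#' Round-trip property: `load_lexicon(save_lexicon(L))` is structurally
#' identical to `L` (for CSV, up to the policy and version, which the CSV
#' dialect does not carry and must be re-supplied on load).
#'
#' @param lx a valid `om_lexicon`.
#' @param path output file path.
#' @param format "yaml" or "csv"; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lx, path, format = c("auto", "yaml", "csv")) {
  validate_lexicon(lx)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     yaml = , yml = "yaml",
                     csv = "csv",
                     stop("cannot infer lexicon format from ", sQuote(path),
                          call. = FALSE))
  }
  if (format == "yaml") {
    df_to_list <- function(df) {
      lapply(seq_len(nrow(df)), function(i) {
        row <- as.list(df[i, , drop = FALSE])
        row <- lapply(row, function(v) if (is.na(v)) NULL else v)
        Filter(Negate(is.null), row)
      })
    }
    doc <- list(
      version = lx$version,
      policy = list(mode = lx$policy$mode,
                    window_tokens = lx$policy$window_tokens,
                    bidirectional = lx$policy$bidirectional),
      search_terms = df_to_list(lx$search_terms),
      exclusion_words = df_to_list(lx$exclusion_words)
    )
    yaml::write_yaml(doc, path)
  } else {
    st <- lx$search_terms
    ex <- lx$exclusion_words
    out <- rbind(
      data.frame(kind = rep("search", nrow(st)), surface = st$surface,
                 case_sensitive = st$case_sensitive, note = st$note,
                 stringsAsFactors = FALSE),
      data.frame(kind = rep("exclusion", nrow(ex)), surface = ex$surface,
                 case_sensitive = ex$case_sensitive, note = NA_character_,
                 stringsAsFactors = FALSE)
    )
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Merge two lexicons
#'
#' Union of search terms and exclusion words with duplicates collapsed
#' (base order first, then novel update entries). The policy is taken from
#' `update`; the version label records both parents. A surface carrying
#' conflicting `case_sensitive` flags across the two inputs is an error
#' demanding explicit resolution, because the two flags define different
#' matching behaviour.
#'
#' @param base,update valid `om_lexicon` objects.
#' @return The merged `om_lexicon`.
#' @export
merge_lexicons <- function(base, update) {
  validate_lexicon(base)
  validate_lexicon(update)
  merge_frame <- function(a, b, label) {
    both <- intersect(a$surface, b$surface)
    conflicts <- both[vapply(both, function(s) {
      !setequal(a$case_sensitive[a$surface == s],
                b$case_sensitive[b$surface == s])
    }, logical(1))]
    if (length(conflicts)) {
      stop(sprintf(
        "merge conflict in %s: case_sensitive differs for %s; resolve explicitly",
        label, paste(sQuote(conflicts), collapse = ", ")), call. = FALSE)
    }
    out <- rbind(a, b[, names(a), drop = FALSE])
    out[!duplicated(paste(out$surface, out$case_sensitive, sep = "\r")), ,
        drop = FALSE]
  }
  st <- merge_frame(base$search_terms, update$search_terms, "search_terms")
  ex <- merge_frame(base$exclusion_words, update$exclusion_words,
                    "exclusion_words")
  version <- if (identical(base$version, update$version)) base$version else
    paste0("merge(", base$version, "+", update$version, ")")
  lexicon(st, ex, policy = update$policy, version = version)
}

#' The shipped seed lexicon
#'
#' Loads the seed rule set distributed with the package
#' (`inst/extdata/seed_lexicon.yaml`). Terms attested in the source study's
#' running text ('otitis media', the tympanic-membrane variants 'T/M',
#' 't/m', 'tm', 'TM', the ambiguous abbreviation 'ROM', and the exclusion
#' word 'normal') are marked as such in the `note` column; the remainder of
#' the list is a synthetic completion with clinically standard OM
#' abbreviations, since the study's full term tables are not public.
#'
#' @return A validated `om_lexicon`.
#' @export
seed_lexicon <- function() {
  load_lexicon(system.file("extdata", "seed_lexicon.yaml",
                           package = "omscreen", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_logical <- function(x, what) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out))) {
    stop("unparseable logical in column ", sQuote(what), ": ",
         paste(sQuote(unique(x[is.na(out)])), collapse = ", "),
         call. = FALSE)
  }
  out
}
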
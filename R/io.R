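#' Read visit records from JSONL or CSV
#'
#' JSONL: one object per line with keys `child_id`, `visit_id`,
#' `visit_date`, `text`. CSV: identical headers, UTF-8. `visit_date` is
#' optional (may be missing or empty); `text` is always returned as a
#' character column with `NA` mapped to `""`.
#'
#' @param path input file.
#' @param format "jsonl" or "csv"; default inferred from the extension.
#' @return data.frame with columns child_id, visit_id, visit_date, text.
#' @export
read_visit_records <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     jsonl = , json = , ndjson = "jsonl",
                     csv = "csv",
                     stop("cannot infer record format from ", sQuote(path),
                          call. = FALSE))
  }
  if (!file.exists(path)) {
    stop("records file not found: ", sQuote(path), call. = FALSE)
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
        stop(sprintf("malformed JSONL at line %d of %s: %s", i, path,
                     conditionMessage(e)), call. = FALSE)
      })
      if (is.null(obj$visit_id)) {
        stop(sprintf("malformed JSONL at line %d of %s: missing visit_id",
                     i, path), call. = FALSE)
      }
      data.frame(
        child_id = as.character(obj$child_id %||% NA),
        visit_id = as.character(obj$visit_id),
        visit_date = as.character(obj$visit_date %||% NA),
        text = as.character(obj$text %||% ""),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    need <- c("child_id", "visit_id", "text")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("records CSV missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!"visit_date" %in% names(df)) df$visit_date <- NA_character_
    df <- df[, c("child_id", "visit_id", "visit_date", "text")]
  }
  df$text[is.na(df$text)] <- ""
  df
}

#' Write visit records
#'
#' @param records data.frame with columns child_id, visit_id, visit_date,
#'   text.
#' @param path output file.
#' @param format "jsonl" or "csv"; default inferred from the extension.
#' @return `path`, invisibly.
#' @rdname read_visit_records
#' @export
write_visit_records <- function(records, path,
                                format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     jsonl = , json = , ndjson = "jsonl",
                     csv = "csv",
                     stop("cannot infer record format from ", sQuote(path),
                          call. = FALSE))
  }
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(
        child_id = records$child_id[i], visit_id = records$visit_id[i],
        visit_date = records$visit_date[i], text = records$text[i]
      ), auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(
      records[, c("child_id", "visit_id", "visit_date", "text")], path,
      row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read gold-standard labels
#'
#' CSV with headers `visit_id`, `om_considered` (true/false or 1/0).
#'
#' @param path input CSV.
#' @return data.frame with columns visit_id (character), om_considered
#'   (logical).
#' @export
read_gold_labels <- function(path) {
  if (!file.exists(path)) {
    stop("gold label file not found: ", sQuote(path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("visit_id", "om_considered")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gold CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data.frame(visit_id = df$visit_id,
             om_considered = parse_logical(df$om_considered,
                                           "om_considered"),
             stringsAsFactors = FALSE)
}

#' @param gold data.frame with visit_id and om_considered.
#' @rdname read_gold_labels
#' @export
write_gold_labels <- function(gold, path) {
  utils::write.csv(
    data.frame(visit_id = gold$visit_id,
               om_considered = tolower(as.character(gold$om_considered))),
    path, row.names = FALSE)
  invisible(path)
}

#' Write / read screening results as JSONL
#'
#' One object per visit with full match provenance
#' (`{visit_id, flagged, matches: [{surface, case_sensitive, start, end,
#' excluded, excl_surface, excl_start, excl_end}]}`).
#' `flagged_only = TRUE` restricts the export to flagged visits, the form
#' handed to the clinician-review stage.
#'
#' @param screen an `om_screen_set` from [screen_corpus()].
#' @param path output file.
#' @param flagged_only write only flagged visits.
#' @return `path` (write) / a data.frame of visit_id, flagged plus a
#'   `matches` attribute (read), invisibly for the writer.
#' @export
write_screen_results <- function(screen, path, flagged_only = FALSE) {
  stopifnot(inherits(screen, "om_screen_set"))
  results <- screen$results
  if (flagged_only) results <- Filter(function(r) r$flagged, results)
  lines <- vapply(results, function(r) {
    m <- r$matches
    jsonlite::toJSON(list(
      visit_id = r$visit_id, flagged = r$flagged,
      matches = lapply(seq_len(nrow(m)), function(i) {
        row <- list(surface = m$surface[i],
                    case_sensitive = m$case_sensitive[i],
                    start = m$start[i], end = m$end[i],
                    excluded = m$excluded[i])
        if (m$excluded[i]) {
          row$excl_surface <- m$excl_surface[i]
          row$excl_start <- m$excl_start[i]
          row$excl_end <- m$excl_end[i]
        }
        row
      })
    ), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_screen_results
#' @export
read_screen_results <- function(path) {
  if (!file.exists(path)) {
    stop("results file not found: ", sQuote(path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) {
               stop(sprintf("malformed results JSONL at line %d: %s", i,
                            conditionMessage(e)), call. = FALSE)
             })
  })
  out <- data.frame(
    visit_id = vapply(objs, function(o) as.character(o$visit_id),
                      character(1)),
    flagged = vapply(objs, function(o) isTRUE(o$flagged), logical(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "matches") <- lapply(objs, `[[`, "matches")
  out
}
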
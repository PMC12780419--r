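#' Confusion matrix for screen-vs-gold comparison
#'
#' @param tp,fp,fn,tn non-negative integer cell counts: tp = flagged and
#'   gold positive, fp = flagged and gold negative, fn = not flagged and
#'   gold positive, tn = not flagged and gold negative.
#' @return An `om_confusion` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "om_confusion")
}

#' @export
print.om_confusion <- function(x, ...) {
  cat("<om_confusion>            gold + gold -\n")
  cat(sprintf("  flagged            %7d %7d\n", x$tp, x$fp))
  cat(sprintf("  not flagged        %7d %7d\n", x$fn, x$tn))
  cat(sprintf("  total %d\n", x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Cross-tabulate screening results against gold-standard labels
#'
#' Every result visit_id must have a gold label and vice versa; orphans on
#' either side are an error (no silent dropping), listing the offending ids.
#'
#' @param results an `om_screen_set` from [screen_corpus()], or a data.frame
#'   with columns `visit_id` and `flagged`.
#' @param gold data.frame with columns `visit_id` and `om_considered`
#'   (logical).
#' @return An `om_confusion`.
#' @export
build_confusion <- function(results, gold) {
  flags <- if (inherits(results, "om_screen_set")) results$flags else results
  stopifnot(is.data.frame(flags), all(c("visit_id", "flagged") %in%
                                        names(flags)))
  stopifnot(is.data.frame(gold), all(c("visit_id", "om_considered") %in%
                                       names(gold)))
  if (nrow(flags) == 0L || nrow(gold) == 0L) {
    stop("no visits to evaluate", call. = FALSE)
  }
  if (anyDuplicated(gold$visit_id)) {
    stop("duplicate visit_id in gold labels", call. = FALSE)
  }
  orphan_res <- setdiff(flags$visit_id, gold$visit_id)
  orphan_gold <- setdiff(gold$visit_id, flags$visit_id)
  if (length(orphan_res) || length(orphan_gold)) {
    stop("visit_id mismatch between results and gold labels:\n",
         if (length(orphan_res)) paste0("  results without gold: ",
           paste(utils::head(orphan_res, 10), collapse = ", "), "\n") else "",
         if (length(orphan_gold)) paste0("  gold without results: ",
           paste(utils::head(orphan_gold, 10), collapse = ", ")) else "",
         call. = FALSE)
  }
  g <- as.logical(gold$om_considered[match(flags$visit_id, gold$visit_id)])
  f <- as.logical(flags$flagged)
  confusion_matrix(tp = sum(f & g), fp = sum(f & !g),
                   fn = sum(!f & g), tn = sum(!f & !g))
}

#' Interval estimate container
#'
#' @param point,lower,upper numeric; `NA` with a `degenerate` reason when
#'   the estimate is undefined (zero denominator / zero cell).
#' @param level confidence level in (0, 1).
#' @param degenerate optional character reason; marks the estimate as
#'   undefined rather than numeric.
#' @return An `om_interval`.
#' @export
interval_estimate <- function(point, lower, upper, level,
                              degenerate = NULL) {
  stopifnot(level > 0, level < 1)
  if (is.null(degenerate) &&
      (is.na(point) || lower > point + 1e-12 || upper < point - 1e-12)) {
    stop("interval must contain its point estimate", call. = FALSE)
  }
  structure(list(point = point, lower = lower, upper = upper, level = level,
                 degenerate = degenerate),
            class = "om_interval")
}

#' @export
print.om_interval <- function(x, digits = 4, ...) {
  if (!is.null(x$degenerate)) {
    cat(sprintf("<om_interval> degenerate: %s\n", x$degenerate))
  } else {
    cat(sprintf("<om_interval> %.*f (%g%% CI %.*f to %.*f)\n", digits,
                x$point, 100 * x$level, digits, x$lower, digits, x$upper))
  }
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Beta-quantile formulation of the exact interval:
#' lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with lower = 0 exactly when k = 0 and upper = 1 exactly when k = n.
#'
#' @param successes,trials counts with 0 <= successes <= trials,
#'   trials >= 1.
#' @param level confidence level (default 0.95).
#' @return An `om_interval` on the proportion scale.
#' @export
proportion_ci <- function(successes, trials, level = 0.95) {
  if (length(trials) != 1L || is.na(trials) || trials < 1) {
    stop("proportion_ci: trials must be >= 1", call. = FALSE)
  }
  if (is.na(successes) || successes < 0 || successes > trials) {
    stop("proportion_ci: need 0 <= successes <= trials", call. = FALSE)
  }
  k <- successes; n <- trials
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  interval_estimate(point = k / n, lower = lower, upper = upper,
                    level = level)
}

#' Log-method confidence interval for a likelihood ratio
#'
#' Delta-method interval on the log scale. For LR+ the variance of
#' ln LR+ is `1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)`; for LR- it is
#' `1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)`. Bounds are
#' `exp(ln(point) +/- z * sqrt(var))`. A zero cell makes the LR infinite,
#' zero, or its variance undefined; such estimates are returned as an
#' explicit degenerate signal, not a number. An optional Haldane correction
#' (+0.5 to every cell) is available but off by default.
#'
#' @param cm an `om_confusion`.
#' @param which "positive" or "negative".
#' @param level confidence level (default 0.95).
#' @param correction "none" (default) or "haldane".
#' @return An `om_interval` on the ratio scale.
#' @export
lr_ci <- function(cm, which = c("positive", "negative"), level = 0.95,
                  correction = c("none", "haldane")) {
  stopifnot(inherits(cm, "om_confusion"))
  which <- match.arg(which)
  correction <- match.arg(correction)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (correction == "haldane") {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  needed <- if (which == "positive") c(tp = tp, fp = fp) else
    c(fn = fn, tn = tn)
  if (any(needed == 0) || (tp + fn) == 0 || (fp + tn) == 0) {
    return(interval_estimate(NA_real_, NA_real_, NA_real_, level,
                             degenerate = sprintf(
                               "LR%s undefined: zero cell (%s)",
                               if (which == "positive") "+" else "-",
                               paste(names(needed)[needed == 0],
                                     collapse = ", "))))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  if (which == "positive") {
    point <- sens / (1 - spec)
    v <- 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
  } else {
    point <- (1 - sens) / spec
    v <- 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  interval_estimate(point = point,
                    lower = point * exp(-z * sqrt(v)),
                    upper = point * exp(z * sqrt(v)),
                    level = level)
}

#' Full diagnostic-accuracy panel
#'
#' Sensitivity, specificity, positive and negative predictive values (each
#' with Clopper-Pearson exact intervals), positive and negative likelihood
#' ratios (log-method intervals), and the workload-reduction proportion.
#' Any undefined estimate (zero denominator) is carried through as a
#' degenerate interval without aborting the others.
#'
#' @param cm an `om_confusion` with total >= 1.
#' @param level confidence level (default 0.95).
#' @param correction LR zero-cell handling, see [lr_ci()].
#' @return An `om_diagnostics` list: `cm`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `lr_positive`, `lr_negative` (all `om_interval`),
#'   `workload_reduction`, `n_flagged`, `n_total`, `level`.
#' @export
diagnostic_stats <- function(cm, level = 0.95,
                             correction = c("none", "haldane")) {
  stopifnot(inherits(cm, "om_confusion"))
  correction <- match.arg(correction)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)

  prop_or_degenerate <- function(k, n, what) {
    if (n == 0) {
      interval_estimate(NA_real_, NA_real_, NA_real_, level,
                        degenerate = paste0(what, " undefined: 0 denominator"))
    } else proportion_ci(k, n, level)
  }
  structure(
    list(
      cm = cm,
      sensitivity = prop_or_degenerate(cm$tp, cm$tp + cm$fn, "sensitivity"),
      specificity = prop_or_degenerate(cm$tn, cm$tn + cm$fp, "specificity"),
      ppv = prop_or_degenerate(cm$tp, cm$tp + cm$fp, "ppv"),
      npv = prop_or_degenerate(cm$tn, cm$tn + cm$fn, "npv"),
      lr_positive = lr_ci(cm, "positive", level, correction),
      lr_negative = lr_ci(cm, "negative", level, correction),
      workload_reduction = workload_reduction(cm),
      n_flagged = cm$tp + cm$fp,
      n_total = total,
      level = level
    ),
    class = "om_diagnostics"
  )
}

#' Workload reduction achieved by the screen
#'
#' The fraction of corpus visits the algorithm removes from clinician
#' review: `1 - (tp + fp) / total`. In the source validation this is the
#' reduction from reviewing every visit to reviewing only flagged ones.
#'
#' @param cm an `om_confusion` with total >= 1.
#' @return A proportion in \[0, 1\].
#' @export
workload_reduction <- function(cm) {
  stopifnot(inherits(cm, "om_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  1 - (cm$tp + cm$fp) / total
}

fmt_interval <- function(x, pct = TRUE, digits = 2) {
  if (!is.null(x$degenerate)) return(paste0("degenerate: ", x$degenerate))
  s <- if (pct) 100 else 1
  unit <- if (pct) "%" else ""
  sprintf("%.*f%s (%.*f%s to %.*f%s)", digits, s * x$point, unit,
          digits, s * x$lower, unit, digits, s * x$upper, unit)
}

#' @param x an `om_diagnostics` object.
#' @param style "table" prints percentages to 2 decimal places; "abstract"
#'   rounds proportions to whole percentages (likelihood ratios stay at
#'   2 dp in both styles).
#' @param ... unused.
#' @rdname diagnostic_stats
#' @export
print.om_diagnostics <- function(x, style = c("table", "abstract"), ...) {
  style <- match.arg(style)
  d <- if (style == "table") 2 else 0
  cat(sprintf("Diagnostic performance (n = %d visits, %d flagged, %g%% CIs)\n",
              x$n_total, x$n_flagged, 100 * x$level))
  cat("  Sensitivity               ", fmt_interval(x$sensitivity, TRUE, d), "\n")
  cat("  Specificity               ", fmt_interval(x$specificity, TRUE, d), "\n")
  cat("  Positive predictive value ", fmt_interval(x$ppv, TRUE, d), "\n")
  cat("  Negative predictive value ", fmt_interval(x$npv, TRUE, d), "\n")
  cat("  Positive likelihood ratio ", fmt_interval(x$lr_positive, FALSE, 2), "\n")
  cat("  Negative likelihood ratio ", fmt_interval(x$lr_negative, FALSE, 2), "\n")
  cat(sprintf("  Workload reduction         %.0f%% (%d of %d visits need review)\n",
              100 * x$workload_reduction, x$n_flagged, x$n_total))
  invisible(x)
}

#' Serialize a diagnostics panel
#'
#' `as.list()` gives a full-precision nested list suitable for JSON export;
#' `diagnostics_markdown()` renders a Markdown table mirroring the
#' validation panel layout.
#'
#' @param x an `om_diagnostics`.
#' @param ... unused.
#' @export
as.list.om_diagnostics <- function(x, ...) {
  iv <- function(e) {
    if (!is.null(e$degenerate)) list(degenerate = e$degenerate) else
      list(point = e$point, lower = e$lower, upper = e$upper)
  }
  list(
    confusion = list(tp = x$cm$tp, fp = x$cm$fp, fn = x$cm$fn, tn = x$cm$tn),
    level = x$level,
    sensitivity = iv(x$sensitivity), specificity = iv(x$specificity),
    ppv = iv(x$ppv), npv = iv(x$npv),
    lr_positive = iv(x$lr_positive), lr_negative = iv(x$lr_negative),
    workload_reduction = x$workload_reduction,
    n_flagged = x$n_flagged, n_total = x$n_total
  )
}

#' @rdname as.list.om_diagnostics
#' @export
diagnostics_markdown <- function(x) {
  stopifnot(inherits(x, "om_diagnostics"))
  c(
    "| Parameter | Estimate (95% CI) |",
    "|---|---|",
    sprintf("| Sensitivity | %s |", fmt_interval(x$sensitivity)),
    sprintf("| Specificity | %s |", fmt_interval(x$specificity)),
    sprintf("| Positive predictive value | %s |", fmt_interval(x$ppv)),
    sprintf("| Negative predictive value | %s |", fmt_interval(x$npv)),
    sprintf("| Positive likelihood ratio | %s |",
            fmt_interval(x$lr_positive, pct = FALSE)),
    sprintf("| Negative likelihood ratio | %s |",
            fmt_interval(x$lr_negative, pct = FALSE)),
    sprintf("| Workload reduction | %.0f%% (%d of %d) |",
            100 * x$workload_reduction, x$n_flagged, x$n_total)
  )
}
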
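#' Confusion counts for binary reporting predictions
#'
#' True positive: the record reports the item and is predicted reported;
#' true negative: does not report and predicted unreported; false positive:
#' does not report but predicted reported; false negative: reports but
#' predicted unreported.
#'
#' @param labels 0/1 vector of gold labels.
#' @param preds 0/1 vector of predictions, same length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, preds) {
  if (length(labels) != length(preds)) {
    stop("labels and predictions have different lengths")
  }
  labels <- as.integer(labels); preds <- as.integer(preds)
  structure(list(tp = sum(labels == 1 & preds == 1),
                 fp = sum(labels == 0 & preds == 1),
                 tn = sum(labels == 0 & preds == 0),
                 fn = sum(labels == 1 & preds == 0)),
            class = "confusion_counts")
}

#' @exportS3Method base::print
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: tp %d, fp %d, tn %d, fn %d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Recall, precision, F1 and specificity from confusion counts
#'
#' Recall = tp/(tp+fn); precision = tp/(tp+fp);
#' F1 = 2*recall*precision/(recall+precision);
#' specificity = tn/(tn+fp). Any 0/0 is defined as 0.
#'
#' @param c A `confusion_counts`, or a list with tp/fp/tn/fn.
#' @return A `metric_set` list with `recall`, `precision`, `f1`,
#'   `specificity`, all in `[0, 1]`.
#' @export
metrics <- function(c) {
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  recall <- safe_div(c$tp, c$tp + c$fn)
  precision <- safe_div(c$tp, c$tp + c$fp)
  f1 <- safe_div(2 * recall * precision, recall + precision)
  specificity <- safe_div(c$tn, c$tn + c$fp)
  structure(list(recall = recall, precision = precision, f1 = f1,
                 specificity = specificity),
            class = "metric_set")
}

#' @exportS3Method base::print
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metrics: F1 %.1f%%, recall %.1f%%, precision %.1f%%, specificity %.1f%%>\n",
    100 * x$f1, 100 * x$recall, 100 * x$precision, 100 * x$specificity))
  invisible(x)
}

#' F1 from recall and precision on the percentage scale
#'
#' Convenience for recomputing table entries reported as percentages to one
#' decimal place.
#'
#' @param recall,precision Percentages (e.g. 59.8).
#' @return F1 as a percentage.
#' @export
f1_from_recall_precision <- function(recall, precision) {
  if (recall + precision == 0) return(0)
  2 * recall * precision / (recall + precision)
}

#' McNemar's test between two classifiers on the same records
#'
#' Discordance is defined on correctness: `b` counts records where model A
#' is correct and model B wrong, `c` the reverse. The default exact method
#' uses the two-sided doubled binomial tail under the symmetric null
#' (equivalent to full enumeration of the `2^(b+c)` discordance outcomes);
#' `"chisq"` gives the continuity-corrected chi-square approximation.
#'
#' @param labels Gold 0/1 labels.
#' @param preds_a,preds_b Predictions of the two classifiers.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return A `mcnemar_result` with `b`, `c`, `p_value`, `method`,
#'   `degenerate` (TRUE when `b + c == 0`, in which case `p_value` is 1).
#' @export
mcnemar_test <- function(labels, preds_a, preds_b,
                         method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- length(labels)
  if (length(preds_a) != n || length(preds_b) != n) {
    stop("labels and both prediction vectors must have equal length")
  }
  ca <- as.integer(preds_a) == as.integer(labels)
  cb <- as.integer(preds_b) == as.integer(labels)
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  degenerate <- (b + c_) == 0
  p <- if (degenerate) {
    1.0
  } else if (method == "exact") {
    min(1, 2 * pbinom(min(b, c_), b + c_, 0.5))
  } else {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c_, p_value = p, method = method,
                 degenerate = degenerate),
            class = "mcnemar_result")
}

#' @exportS3Method base::print
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar (%s): b %d, c %d, p %.4g%s>\n", x$method, x$b,
              x$c, x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Select the best model by validation F1
#'
#' Argmax of F1; ties are broken by higher recall, then by the
#' lexicographically smallest model key, so selection is deterministic.
#'
#' @param metric_sets Named list of `metric_set`s keyed by model.
#' @return The selected model key.
#' @export
select_best <- function(metric_sets) {
  stopifnot(length(metric_sets) > 0)
  keys <- names(metric_sets)
  f1 <- vapply(metric_sets, function(m) m$f1, 0)
  recall <- vapply(metric_sets, function(m) m$recall, 0)
  ord <- order(-f1, -recall, keys)
  keys[ord[1]]
}

#' Per-model evaluation report
#'
#' @param results Named list; each entry a list with `labels`, `preds`, and
#'   optionally `item` and `split`.
#' @return Data frame with columns item, model, split, tp, fp, tn, fn,
#'   recall, precision, f1, specificity (rates as percentages).
#' @export
evaluation_report <- function(results) {
  rows <- lapply(names(results), function(key) {
    r <- results[[key]]
    cc <- confusion(r$labels, r$preds)
    m <- metrics(cc)
    data.frame(item = r$item %||% NA_character_, model = key,
               split = r$split %||% NA_character_,
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               recall = round(100 * m$recall, 1),
               precision = round(100 * m$precision, 1),
               f1 = round(100 * m$f1, 1),
               specificity = round(100 * m$specificity, 1))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
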
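#' Binary-classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, precision, F-score and
#' Matthews correlation coefficient from the four confusion counts.
#'
#' Degenerate cases: when both TP and FP are 0 (nothing predicted positive)
#' the Matthews coefficient is defined as -1, the worst value — the
#' convention used throughout this toolkit. Any other zero denominator
#' (sensitivity, specificity, precision, F-score, or the Matthews product
#' term) yields 0 for that metric and records its name in the `degenerate`
#' field, so cross-validation aggregates stay computable.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts. Alternatively
#'   pass a single named vector/list with elements TP, FP, TN, FN as `tp`.
#' @return An `evaluation_report`: list with `counts` and the six metrics
#'   (`acc`, `sens`, `spec`, `pre`, `f_score`, `mcc`) plus `degenerate`.
#' @export
#' @examples
#' classification_metrics(40, 15, 35, 10)$acc  # 0.75
#' classification_metrics(0, 0, 10, 10)$mcc    # -1
classification_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp)
    names(cc) <- toupper(names(cc))
    tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
  }
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (anyNA(counts) || any(counts < 0)) {
    abort_validation("confusion counts must be non-negative numbers")
  }
  total <- sum(counts)
  if (total == 0) abort_validation("empty evaluation: all confusion counts are 0")

  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }

  acc <- (tp + tn) / total
  sens <- safe(tp, tp + fn, "sens")
  spec <- safe(tn, tn + fp, "spec")
  pre <- safe(tp, tp + fp, "pre")
  f_score <- safe(2 * pre * sens, pre + sens, "f_score")

  if (tp == 0 && fp == 0) {
    mcc <- -1    # nothing predicted positive: poorest predictive ability
  } else {
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- safe(as.numeric(tp) * tn - as.numeric(fp) * fn, den, "mcc")
  }

  structure(list(counts = counts, acc = acc, sens = sens, spec = spec,
                 pre = pre, f_score = f_score, mcc = mcc,
                 degenerate = degenerate),
            class = "evaluation_report")
}

METRIC_NAMES <- c("acc", "sens", "spec", "pre", "f_score", "mcc")

report_metrics <- function(report) {
  vapply(METRIC_NAMES, function(m) report[[m]], numeric(1))
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  TP=%g FP=%g TN=%g FN=%g\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  m <- report_metrics(x)
  cat("  ", paste(sprintf("%s=%.*f", names(m), digits, m), collapse = " "),
      "\n", sep = "")
  if (length(x$degenerate)) {
    cat("  degenerate (set to 0):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Confusion counts from labels and predictions
#'
#' @param truth,pred Vectors of +1/-1 labels of equal length.
#' @return Named integer vector (TP, FP, TN, FN).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    abort_validation("truth and pred must have equal length")
  }
  if (!all(c(truth, pred) %in% c(-1L, 1L))) {
    abort_validation("labels must be +1 or -1")
  }
  c(TP = sum(truth == 1L & pred == 1L),
    FP = sum(truth == -1L & pred == 1L),
    TN = sum(truth == -1L & pred == -1L),
    FN = sum(truth == 1L & pred == -1L))
}

#' Evaluate predictions against true labels
#'
#' @inheritParams confusion_counts
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(truth, pred) {
  classification_metrics(confusion_counts(truth, pred))
}
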
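# One-vs-rest confusion counts and the standard accuracy / precision /
# recall / F1 metrics.

#' Per-class one-vs-rest confusion counts
#'
#' For each class, counts true positives (predicted and actually that
#' class), false positives, false negatives and true negatives over the
#' prediction/truth pair; per class the four counts always sum to the
#' number of samples.
#'
#' @param pred Character/factor vector of predicted labels.
#' @param truth Vector of true labels, same length.
#' @return An object of class `confusion_counts`: a list with `counts`
#'   (tibble: class, tp, fp, fn, tn), `n_classes`, `n_samples`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stopf("pred has %d labels but truth has %d", length(pred), length(truth))
  }
  classes <- sort(unique(c(pred, truth)))
  n <- length(pred)
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  })
  structure(
    list(counts = dplyr::bind_rows(rows),
         n_classes = length(classes), n_samples = n),
    class = "confusion_counts"
  )
}

#' Build confusion counts directly from per-class counts
#'
#' Useful for closed-form checks where the counts, not the label vectors,
#' are the starting point.
#'
#' @param tp,fp,fn,tn Non-negative integer vectors (one entry per class);
#'   per class the four must sum to the same total `n`.
#' @param class Optional class labels (default `"class1"`, ...).
#' @return A `confusion_counts` object.
#' @export
manual_confusion_counts <- function(tp, fp, fn, tn, class = NULL) {
  k <- length(tp)
  stopifnot(length(fp) == k, length(fn) == k, length(tn) == k)
  totals <- tp + fp + fn + tn
  if (length(unique(totals)) != 1) {
    stopf("per-class counts must sum to a common sample total")
  }
  if (is.null(class)) class <- sprintf("class%d", seq_len(k))
  structure(
    list(counts = tibble::tibble(class = class, tp = tp, fp = fp, fn = fn, tn = tn),
         n_classes = k, n_samples = totals[1]),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %d classes, %d samples\n", x$n_classes, x$n_samples))
  print(x$counts)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Per class: accuracy `(TP + TN) / n`, precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)`, and F1 the harmonic mean of precision and
#' recall. `averaging = "macro"` (default) averages the per-class
#' precision/recall and derives F1 from the averages; `"micro"` pools the
#' counts first, so micro accuracy (`sum(TP) / n`) equals the fraction of
#' exactly correct predictions. Classes with a zero denominator contribute
#' 0 with a warning.
#'
#' @param counts A `confusion_counts` object.
#' @param averaging `"macro"` or `"micro"`.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `averaging`.
#' @export
classification_metrics <- function(counts, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(counts, "confusion_counts"))
  ct <- counts$counts
  n <- counts$n_samples
  if (n < 1) stopf("no samples")

  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warnf("%s undefined for %d class(es) (zero denominator); contributing 0",
            what, sum(bad))
    }
    ifelse(bad, 0, num / den)
  }

  if (averaging == "macro") {
    acc <- mean((ct$tp + ct$tn) / n)
    prec <- mean(safe_div(ct$tp, ct$tp + ct$fp, "precision"))
    rec <- mean(safe_div(ct$tp, ct$tp + ct$fn, "recall"))
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  } else {
    tp <- sum(ct$tp); fp <- sum(ct$fp); fn <- sum(ct$fn)
    acc <- tp / n
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  tibble::tibble(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 averaging = averaging)
}
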
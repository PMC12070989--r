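# Segmentation and classification evaluation metrics.

#' Segmentation overlap scores
#'
#' Pixelwise Dice, IoU, precision and recall from TP/FP/FN tallies of a
#' binary predicted mask against a binary ground truth. Two empty masks
#' score 1 on all four metrics by convention (perfect agreement on "no
#' lesion"); a prediction disjoint from a non-empty truth scores 0.
#'
#' @param pred_mask,gt_mask binary (0/1 or logical) matrices of equal shape.
#' @return Named list with `dice`, `iou`, `precision`, `recall`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
segmentation_scores <- function(pred_mask, gt_mask) {
  p <- as.logical(pred_mask); g <- as.logical(gt_mask)
  if (length(p) != length(g) || !identical(dim(pred_mask), dim(gt_mask))) {
    cg_stop("cg_shape_error", "mask shapes differ")
  }
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  if (tp + fp + fn == 0) {
    return(list(dice = 1, iou = 1, precision = 1, recall = 1,
                tp = tp, fp = fp, fn = fn, tn = tn))
  }
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(dice = safe(2 * tp, 2 * tp + fp + fn),
       iou = safe(tp, tp + fp + fn),
       precision = safe(tp, tp + fp),
       recall = safe(tp, tp + fn),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Mean per-pixel binary cross-entropy
#'
#' @param pred_probs numeric array of foreground probabilities in `[0, 1]`.
#' @param gt_mask binary array of the same shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred_probs, gt_mask) {
  if (length(pred_probs) != length(gt_mask)) {
    cg_stop("cg_shape_error", "shapes differ")
  }
  if (any(pred_probs < 0) || any(pred_probs > 1)) {
    cg_stop("cg_domain_error", "predicted probabilities must lie in [0, 1]")
  }
  y <- as.numeric(as.logical(gt_mask))
  p <- pmin(pmax(as.numeric(pred_probs), 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Confusion matrix
#'
#' Entry `(r, c)` counts items of true class `r` predicted as class `c`
#' (0-based classes; matrix dimnames carry the indices).
#'
#' @param true_labels,predicted_labels integer vectors in `[0, C)`.
#' @param n_classes `C`.
#' @return `C x C` integer matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (any(true_labels < 0) || any(true_labels >= n_classes) ||
      any(predicted_labels < 0) || any(predicted_labels >= n_classes)) {
    cg_stop("cg_label_error", "labels out of range [0, %d)", n_classes)
  }
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (k in seq_along(true_labels)) {
    m[true_labels[k] + 1, predicted_labels[k] + 1] <-
      m[true_labels[k] + 1, predicted_labels[k] + 1] + 1L
  }
  m
}

#' One-vs-rest ROC-AUC
#'
#' Trapezoidal integration of the ROC curve obtained by binarizing
#' `class_index` against the rest and thresholding that class's predicted
#' probability at every distinct value (plus sentinels). Equals the
#' Mann-Whitney concordant-pair statistic. Returns `NA` when the
#' binarization is degenerate (only one class present).
#'
#' @param true_labels 0-based integer labels.
#' @param probabilities `N x C` matrix of predicted class probabilities.
#' @param class_index 0-based class to score.
#' @return AUC in `[0, 1]`, or `NA_real_` for degenerate input.
#' @export
roc_auc_ovr <- function(true_labels, probabilities, class_index) {
  y <- as.integer(true_labels == class_index)
  s <- probabilities[, class_index + 1]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(s >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & y == 0) / n_neg, numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# macro F1 helper shared with grid search
macro_f1 <- function(true_labels, predicted_labels, n_classes) {
  f1 <- numeric(n_classes)
  for (c in 0:(n_classes - 1)) {
    tp <- sum(true_labels == c & predicted_labels == c)
    fp <- sum(true_labels != c & predicted_labels == c)
    fn <- sum(true_labels == c & predicted_labels != c)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c + 1] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  mean(f1)
}

#' Full classification metrics report
#'
#' Per-class one-vs-rest precision, recall, F1 and accuracy, overall
#' accuracy, macro averages (arithmetic means of the per-class values),
#' the confusion matrix, and one-vs-rest ROC-AUC per class when
#' probabilities are supplied. A class absent from the true labels gets
#' recall 0 and is flagged in `undefined_recall`.
#'
#' @param true_labels,predicted_labels 0-based integer vectors of equal
#'   length.
#' @param probabilities optional `N x C` probability matrix (rows sum
#'   to 1); enables AUC.
#' @param n_classes `C` (default inferred).
#' @return An object of class `metrics_report`.
#' @export
classification_report <- function(true_labels, predicted_labels,
                                  probabilities = NULL, n_classes = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  C <- n_classes %||% (max(c(true_labels, predicted_labels)) + 1L)
  if (!is.null(probabilities)) {
    stopifnot(nrow(probabilities) == length(true_labels),
              ncol(probabilities) == C)
    if (any(abs(rowSums(probabilities) - 1) > 1e-6)) {
      cg_stop("cg_domain_error", "probability rows must sum to 1")
    }
  }
  N <- length(true_labels)
  cm <- confusion_matrix(true_labels, predicted_labels, C)
  per_class <- data.frame(class = 0:(C - 1), precision = NA_real_,
                          recall = NA_real_, f1 = NA_real_,
                          accuracy = NA_real_, support = NA_integer_,
                          auc = NA_real_)
  undefined_recall <- integer(0)
  for (c in 0:(C - 1)) {
    tp <- cm[c + 1, c + 1]
    fp <- sum(cm[, c + 1]) - tp
    fn <- sum(cm[c + 1, ]) - tp
    tn <- N - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    if (tp + fn == 0) {
      rec <- 0
      undefined_recall <- c(undefined_recall, c)
    } else {
      rec <- tp / (tp + fn)
    }
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    per_class[c + 1, 2:6] <- c(prec, rec, f1, (tp + tn) / N, tp + fn)
    if (!is.null(probabilities)) {
      per_class$auc[c + 1] <- roc_auc_ovr(true_labels, probabilities, c)
    }
  }
  structure(list(
    per_class = per_class,
    accuracy = sum(diag(cm)) / N,
    macro = list(precision = mean(per_class$precision),
                 recall = mean(per_class$recall),
                 f1 = mean(per_class$f1),
                 accuracy = mean(per_class$accuracy)),
    confusion = cm,
    n = N,
    undefined_recall = undefined_recall
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: n=%d, accuracy %.4f, macro F1 %.4f>\n",
              x$n, x$accuracy, x$macro$f1))
  print(round(x$per_class, 4))
  invisible(x)
}

#' Export a metrics report
#'
#' JSON for the full report; the confusion matrix also as CSV when
#' `confusion_csv` is given.
#'
#' @param report a [classification_report()].
#' @param path JSON output path.
#' @param confusion_csv optional CSV path for the confusion matrix.
#' @export
write_metrics_report <- function(report, path, confusion_csv = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  payload <- list(per_class = report$per_class, accuracy = report$accuracy,
                  macro = report$macro, confusion = report$confusion,
                  n = report$n)
  jsonlite::write_json(payload, path, digits = 10, auto_unbox = TRUE)
  if (!is.null(confusion_csv)) {
    utils::write.csv(report$confusion, confusion_csv)
  }
  invisible(path)
}

#' Class imbalance ratio
#'
#' Largest class count divided by the smallest; the display value is
#' rounded half-up to 2 decimals as conventionally printed.
#'
#' @param class_counts positive integer vector.
#' @return List with `exact` and `rounded`.
#' @export
imbalance_ratio <- function(class_counts) {
  if (any(class_counts <= 0)) {
    cg_stop("cg_domain_error", "class counts must be positive")
  }
  exact <- max(class_counts) / min(class_counts)
  list(exact = exact, rounded = floor(exact * 100 + 0.5) / 100)
}
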
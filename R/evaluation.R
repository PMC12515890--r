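# Evaluation: confusion matrices and the five per-class one-vs-rest metrics
# (accuracy, precision, recall/sensitivity, F1, specificity), with per-class
# and macro-averaged reports.

#' Confusion matrix from predicted and true class indices
#'
#' @param predictions integer vector of predicted classes, `0 .. K-1`.
#' @param labels integer vector of true classes, same length.
#' @param K number of classes.
#' @param class_names optional dimnames.
#' @return A `K x K` integer matrix of class `oct_confusion`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion_matrix <- function(predictions, labels, K, class_names = NULL) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  if (any(predictions < 0L | predictions >= K) || any(labels < 0L | labels >= K)) {
    stop("class indices must lie in 0..K-1")
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(labels)) {
    cm[labels[i] + 1L, predictions[i] + 1L] <-
      cm[labels[i] + 1L, predictions[i] + 1L] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  class(cm) <- c("oct_confusion", class(cm))
  cm
}

# One-vs-rest counts for one class (1-based index into the matrix).
ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' One-vs-rest metrics for a single class
#'
#' Treating `class_id` as positive and all others as negative:
#' Acc = (TP+TN)/n, Pre = TP/(TP+FP), Rec = TP/(TP+FN),
#' FS = 2*Pre*Rec/(Pre+Rec), Spe = TN/(TN+FP). Zero-denominator cases
#' return 0 with a `degenerate` attribute flag.
#'
#' @param cm a [confusion_matrix()].
#' @param class_id 0-based class index.
#' @return Named numeric vector (Acc, Pre, Rec, FS, Spe).
#' @export
class_metrics <- function(cm, class_id) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  if (class_id < 0L || class_id >= K) stop("class_id out of range")
  ct <- ovr_counts(cm, class_id + 1L)
  pre <- safe_div(ct["TP"], ct["TP"] + ct["FP"])
  rec <- safe_div(ct["TP"], ct["TP"] + ct["FN"])
  out <- c(
    Acc = unname(safe_div(ct["TP"] + ct["TN"], sum(ct))),
    Pre = unname(pre),
    Rec = unname(rec),
    FS = unname(safe_div(2 * pre * rec, pre + rec)),
    Spe = unname(safe_div(ct["TN"], ct["TN"] + ct["FP"]))
  )
  attr(out, "degenerate") <- (ct["TP"] + ct["FP"]) == 0 ||
    (ct["TP"] + ct["FN"]) == 0 || (ct["TN"] + ct["FP"]) == 0
  out
}

#' Per-class and averaged metrics report
#'
#' @param cm a [confusion_matrix()].
#' @param average `"macro"` (unweighted mean over classes, the default) or
#'   `"weighted"` (by class support).
#' @return A list with `per_class` (data frame, one row per class) and
#'   `average` (one row).
#' @export
metrics_report <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  K <- nrow(cm)
  per <- t(vapply(0:(K - 1L), function(k) class_metrics(cm, k), numeric(5)))
  per_df <- data.frame(class = rownames(cm) %||% paste0("class", 0:(K - 1L)),
                       n = rowSums(cm), per, stringsAsFactors = FALSE)
  avg <- if (average == "macro") average_metrics(per_df)
         else colSums(per * rowSums(cm)) / sum(cm)
  list(per_class = per_df, average = as.data.frame(as.list(avg)),
       averaging = average)
}

#' Macro-average a per-class metrics table
#'
#' Unweighted arithmetic mean of each metric column over classes.
#'
#' @param report the `per_class` data frame of [metrics_report()] (or any
#'   data frame with Acc/Pre/Rec/FS/Spe columns).
#' @export
average_metrics <- function(report) {
  cols <- intersect(c("Acc", "Pre", "Rec", "FS", "Spe"), names(report))
  if (!length(cols)) stop("no metric columns found")
  colMeans(report[, cols, drop = FALSE])
}

#' Evaluate a fitted model on one split
#'
#' @param fit an [oct_fit()].
#' @param index an `oct_index`.
#' @param split split to evaluate (default `"test"`).
#' @param best use best-on-validation weights.
#' @return List with `accuracy`, `confusion` and `report`.
#' @export
evaluate_model <- function(fit, index, split = "test", best = FALSE) {
  rows <- which(index$split == split)
  if (!length(rows)) stop("empty split: ", split)
  preds <- predict(fit, index, split = split, type = "class", best = best)
  labs <- index$label[rows]
  K <- length(attr(index, "class_names"))
  cm <- confusion_matrix(preds, labs, K, attr(index, "class_names"))
  list(accuracy = mean(preds == labs), confusion = cm,
       report = metrics_report(cm))
}

#' @export
print.oct_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}
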
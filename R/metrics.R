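# Frame-level evaluation metrics: confusion counts, accuracy / precision /
# recall / F1 in the exact count forms, and non-interpolated average
# precision over the ranked per-frame scores.

#' Frame-level confusion counts
#'
#' @param pred_labels,true_labels equal-length 0/1 vectors.
#' @return named integer vector `TP`, `FP`, `TN`, `FN` (summing to the
#'   number of frames).
#' @export
confusion_counts <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop("pred_labels (", length(pred_labels), ") and true_labels (",
         length(true_labels), ") differ in length")
  }
  p <- as.integer(pred_labels); y <- as.integer(true_labels)
  c(TP = sum(p == 1L & y == 1L), FP = sum(p == 1L & y == 0L),
    TN = sum(p == 0L & y == 0L), FN = sum(p == 0L & y == 1L))
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FN+FP); recall = TP/(TP+FN);
#' precision = TP/(TP+FP); F1 = TP/(TP + (FP+FN)/2), which equals the
#' harmonic mean of precision and recall whenever both are defined.
#' Metrics with a zero denominator are reported as `NA` and named in the
#' `undefined` element — never silently 0 or 1.
#'
#' @param TP,FP,TN,FN non-negative counts, not all zero. `TP` may also be the
#'   named vector from [confusion_counts()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `undefined`.
#' @export
classification_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4) {
    cc <- TP; TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  }
  tot <- TP + FP + TN + FN
  if (any(c(TP, FP, TN, FN) < 0) || tot == 0) {
    stop("confusion counts must be non-negative with a positive sum")
  }
  undef <- character(0)
  acc <- (TP + TN) / tot
  prec <- if (TP + FP > 0) TP / (TP + FP) else { undef <- c(undef, "precision"); NA_real_ }
  rec <- if (TP + FN > 0) TP / (TP + FN) else { undef <- c(undef, "recall"); NA_real_ }
  f1 <- if (TP + FP + FN > 0) TP / (TP + 0.5 * (FP + FN)) else {
    undef <- c(undef, "f1"); NA_real_
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       undefined = undef)
}

#' Average precision (area under the precision-recall curve)
#'
#' Non-interpolated AP: frames are ranked by descending score (ties keep
#' their original order) and AP is the mean, over the positive frames, of the
#' precision at each positive's rank. Upper bound 1; threshold-free, so
#' particularly informative under the severe class imbalance of frame-level
#' phase detection.
#'
#' @param scores per-frame positive-class scores.
#' @param true_labels 0/1 vector, at least one positive.
#' @export
average_precision <- function(scores, true_labels) {
  if (length(scores) != length(true_labels)) stop("length mismatch")
  y <- as.integer(true_labels)
  npos <- sum(y == 1L)
  if (npos == 0) stop("average precision is undefined with zero positive labels")
  ord <- order(-scores)                 # stable: ties keep original order
  ys <- y[ord]
  prec_at_k <- cumsum(ys) / seq_along(ys)
  sum(prec_at_k[ys == 1L]) / npos
}

#' Mean and sample standard deviation of repeated metric values
#'
#' @param values numeric vector of per-repeat values.
#' @param digits rounding applied for presentation (3 to match the reporting
#'   convention); the unrounded values are kept alongside.
#' @export
aggregate_metric <- function(values, digits = 3) {
  m <- mean(values, na.rm = TRUE)
  s <- if (sum(!is.na(values)) > 1) sd(values, na.rm = TRUE) else 0
  list(mean = m, sd = s,
       mean_rounded = round(m, digits), sd_rounded = round(s, digits))
}
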
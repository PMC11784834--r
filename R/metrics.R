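#' Confusion counts
#'
#' Square contingency matrix of true vs. predicted class, with the
#' per-class binary reductions (TP, TN, FP, FN) available via
#' [binary_counts()].
#'
#' @param truth,pred Label vectors of equal length (any common coding).
#' @param classes Optional class universe (defaults to the observed union).
#' @return `confusion_counts` object: a counts matrix (rows = truth).
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred))
    stop("confusion_counts: length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  structure(unclass(as.matrix(m)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (rows = truth, cols = predicted):\n")
  print(matrix(unclass(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Per-class binary reduction of a confusion matrix
#'
#' @param cc A [confusion_counts()] matrix.
#' @param class Class (row/column name or index).
#' @return Named vector `c(TP, TN, FP, FN)`.
#' @export
binary_counts <- function(cc, class) {
  i <- if (is.character(class)) match(class, rownames(cc)) else class
  TP <- cc[i, i]
  FN <- sum(cc[i, ]) - TP
  FP <- sum(cc[, i]) - TP
  TN <- sum(cc) - TP - FN - FP
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` for binary counts; for a multi-class
#' confusion matrix this is the overall accuracy `trace / total`, which
#' coincides with the binary formula when the matrix is 2 x 2.
#'
#' @param cc A [confusion_counts()] matrix, or a named vector with
#'   components `TP`, `TN`, `FP`, `FN`.
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' accuracy(c(TP = 50, TN = 50, FP = 0, FN = 0))  # 1
accuracy <- function(cc) {
  if (is.numeric(cc) && !is.matrix(cc) &&
      all(c("TP", "TN", "FP", "FN") %in% names(cc))) {
    tot <- sum(cc[c("TP", "TN", "FP", "FN")])
    if (tot == 0) stop("accuracy: empty counts (undefined metric)")
    return(unname((cc["TP"] + cc["TN"]) / tot))
  }
  tot <- sum(cc)
  if (tot == 0) stop("accuracy: empty counts (undefined metric)")
  sum(diag(as.matrix(cc))) / tot
}

#' Sample standard deviation of per-subject scores
#'
#' `sqrt(sum((x_i - mean)^2) / (n - 1))`; the dispersion reported next to
#' mean accuracy in subject-wise evaluation. Undefined (NA) for a single
#' score.
#'
#' @param x Numeric score vector.
#' @return Sample standard deviation, or `NA_real_` when `length(x) < 2`.
#' @export
#' @examples
#' score_std(c(1, 2, 3))  # 1
score_std <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}
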
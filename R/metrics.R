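#' Confusion counts and threshold metrics at a probability cutoff
#'
#' Cases (label +1) are condition-positive. Predictions are positive when
#' the calibrated probability is at or above `cutoff`. Reports
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)` and `F1 = 2TP/(2TP+FP+FN)`.
#'
#' @param labels vector in \{-1, +1\}.
#' @param probabilities values in [0, 1].
#' @param cutoff decision threshold (default 0.5).
#' @return a `metrics_report` list with TP, TN, FP, FN and the four metrics.
#' @export
confusion_and_metrics <- function(labels, probabilities, cutoff = 0.5) {
  if (!length(labels)) stop("empty input")
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(-1, 1)),
            all(probabilities >= 0 & probabilities <= 1))
  pred <- probabilities >= cutoff
  pos <- labels == 1
  tp <- sum(pred & pos); tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 f1 = 2 * tp / (2 * tp + fp + fn)),
            class = "metrics_report")
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random case scores above a random control, with tied
#' scores counted half; identical to the trapezoidal area under the ROC
#' curve over all thresholds.
#'
#' @param labels vector in \{-1, +1\} with both classes present.
#' @param scores real-valued scores or probabilities (rank-invariant).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Splits subjects into `k` folds preserving the class balance; every fold
#' receives at least one subject from each class (an error otherwise).
#'
#' @param y labels in \{-1, +1\}.
#' @param k number of folds.
#' @param seed RNG seed (assignment is deterministic given `y`, `k`, `seed`).
#' @return list of `k` integer index vectors (the held-out sets).
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- split(seq_along(y), fold_of)
  names(folds) <- NULL
  if (length(folds) != k) stop("could not build ", k, " non-empty folds")
  ok <- vapply(folds, function(f) length(unique(y[-f])) == 2L &&
                 length(unique(y[f])) == 2L, TRUE)
  if (!all(ok))
    stop("some folds are single-class; reduce k or rebalance")
  folds
}
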
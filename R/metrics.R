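## Discrimination metrics for presence/absence scores: AUC in the
## Mann-Whitney pairwise formulation and the true skill statistic maximised
## over candidate thresholds.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of (presence, absence) pairs in which the presence scores
#' higher, ties counted one half. Equivalent to the rank-sum computation
#' used here, which is O(n log n).
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores numeric vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  check_labels(labels, scores)
  pos <- labels == 1
  r <- rank(scores)                       # midranks handle ties as 0.5
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic maximised over thresholds
#'
#' Candidate thresholds are the unique score values; a cell is predicted
#' present iff `score >= t`. TSS = sensitivity + specificity - 1. Returns
#' the maximum and the smallest threshold attaining it.
#'
#' @inheritParams auc_score
#' @return list with elements `tss` and `threshold`.
#' @export
tss_score <- function(labels, scores) {
  check_labels(labels, scores)
  thr <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  # sweep thresholds descending via cumulative counts of sorted scores
  tss <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    sens + spec - 1
  }, 0)
  best <- max(tss)
  list(tss = best, threshold = thr[which(tss == best)[1]])
}

#' TSS from a fixed confusion table
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return sensitivity + specificity - 1.
#' @export
tss_from_confusion <- function(tp, fn, tn, fp) {
  tp / (tp + fn) + tn / (tn + fp) - 1
}

check_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (any(!is.finite(scores))) stop("scores must be finite")
  invisible(TRUE)
}
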
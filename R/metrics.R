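#' Rank-based area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a randomly chosen positive
#' is scored above a randomly chosen negative, with ties counting one half.
#' Equivalently `(concordant + 0.5 * tied) / (n1 * n0)`.
#'
#' @param scores numeric vector, higher = more disease-like.
#' @param labels binary vector (0/1, or logical) of the same length.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' aucRank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-bag error of a balanced random forest
#'
#' Each sample is predicted by the majority vote of the trees for which it
#' was out of the bootstrap bag; the error is the fraction misclassified.
#' Samples that were never out-of-bag (possible with very few trees) are
#' excluded with a warning.
#'
#' @param forest a fitted `randomForest` object (see [fitBalancedRF]).
#' @param y optional true labels; defaults to the labels stored in the
#'   forest.
#' @return a list with `error` (overall OOB misclassification rate),
#'   `perClass` (named per-class error rates), and `excluded` (count of
#'   never-OOB samples).
#' @export
oobError <- function(forest, y = NULL) {
  stopifnot(inherits(forest, "randomForest"))
  if (is.null(y)) y <- forest$y
  y <- factor(y, levels = colnames(forest$votes))
  include <- forest$oob.times > 0L
  if (any(!include))
    warning(sum(!include), " sample(s) never out-of-bag; excluded")
  votes <- forest$votes[include, , drop = FALSE]
  pred <- colnames(votes)[apply(votes, 1L, which.max)]
  truth <- as.character(y[include])
  wrong <- pred != truth
  perClass <- tapply(wrong, truth, mean)
  list(error = mean(wrong),
       perClass = perClass[colnames(forest$votes)],
       excluded = sum(!include))
}

#' Per-class accuracy
#'
#' Fraction of samples of the positive class that were predicted correctly
#' (the melanoma-class accuracy of the study design).
#'
#' @param predicted predicted labels.
#' @param truth true labels of the same length.
#' @param positive the label value counted as positive (default 1).
#' @return fraction in [0, 1].
#' @export
perClassAccuracy <- function(predicted, truth, positive = 1L) {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  if (!any(pos)) stop("no samples of the positive class")
  mean(predicted[pos] == positive)
}
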
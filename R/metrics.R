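#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with tied scores averaged: the probability that a random
#' positive outranks a random negative, plus half the tie probability.
#'
#' @param probs Numeric scores.
#' @param labels Logical (or 0/1) outcomes, `TRUE` = positive; both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)) # 0.75
#' @export
roc_auc <- function(probs, labels) {
  y <- as.logical(labels)
  stopifnot(length(probs) == length(y), !anyNA(probs), !anyNA(y))
  n_pos <- as.numeric(sum(y))
  n_neg <- as.numeric(sum(!y))
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration (average precision): scores are scanned from the highest
#' down, tied scores grouped, and precision is accumulated over each recall
#' increment.
#'
#' @inheritParams roc_auc
#' @return AU-PRC in \[0, 1\].
#' @export
au_prc <- function(probs, labels) {
  y <- as.logical(labels)
  stopifnot(length(probs) == length(y), !anyNA(probs), !anyNA(y))
  n_pos <- sum(y)
  if (n_pos == 0 || n_pos == length(y)) {
    stop("both classes must be present", call. = FALSE)
  }
  o <- order(probs, decreasing = TRUE)
  ys <- y[o]
  ps <- probs[o]
  grp_last <- c(ps[-length(ps)] != ps[-1], TRUE)  # last index of each tie group
  tp <- cumsum(ys)[grp_last]
  n_seen <- seq_along(ys)[grp_last]
  precision <- tp / n_seen
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Baseline AU-PRC of a label set
#'
#' The positive-class prevalence: the AU-PRC of a chance-level scorer.
#'
#' @param labels Logical (or 0/1) outcomes.
#' @return Prevalence in \[0, 1\].
#' @export
baseline_auprc <- function(labels) {
  y <- as.logical(labels)
  stopifnot(length(y) > 0, !anyNA(y))
  mean(y)
}

#' Operating point chosen on the training ROC
#'
#' Scans every achievable threshold (midpoints between adjacent distinct
#' scores, plus the extremes) and returns the one maximising Youden's J
#' (sensitivity + specificity - 1) on the training data; ties are broken
#' toward the higher threshold, i.e. toward higher specificity. A score is
#' called positive when it is `>=` the threshold.
#'
#' @inheritParams roc_auc
#' @return The probability threshold.
#' @export
training_operating_point <- function(probs, labels) {
  y <- as.logical(labels)
  stopifnot(length(probs) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  s <- sort(unique(probs))
  cand <- c(min(s) - 1, (s[-length(s)] + s[-1]) / 2, max(s) + 1)
  j <- vapply(cand, function(th) {
    pred <- probs >= th
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

sens_spec_at <- function(probs, labels, threshold) {
  y <- as.logical(labels)
  pred <- probs >= threshold
  c(sensitivity = if (any(y)) sum(pred & y) / sum(y) else NA_real_,
    specificity = if (any(!y)) sum(!pred & !y) / sum(!y) else NA_real_)
}
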
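#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) auROC with proper tie handling. Returns `NA`
#' (with attribute `undefined = TRUE`) when a split contains no positives
#' or no negatives, rather than propagating NaN.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return auROC in `[0, 1]`, or `NA` when undefined.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over recall increments of the precision at
#' each distinct score threshold, descending. Ties are handled by treating
#' tied scores as a single threshold. Returns `NA` when no positives exist.
#'
#' @inheritParams auroc
#' @return auPR in `[0, 1]`, or `NA` when undefined.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  if (n1 == 0L || length(labels) == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # thresholds at the last element of each tied block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]
  fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

# O(n^2) pairwise-comparison oracle for auROC (ties count 1/2), used in
# tests as the independent reference.
auroc_pairwise <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}
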
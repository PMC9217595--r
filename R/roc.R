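#' Empirical ROC analysis
#'
#' Sweeps every distinct score as a cut-point (predict positive when
#' \code{score >= threshold}), computing sensitivity and specificity at each.
#' The AUC is the trapezoidal area under the resulting curve; because tied
#' scores are handled as a single threshold step, this equals the normalised
#' Mann-Whitney U statistic with the midrank tie convention,
#' \code{P(s+ > s-) + 0.5 P(s+ = s-)}.  The reported operating point
#' maximises the Youden index (sens + spec - 1), ties resolved toward the
#' lower threshold.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels logical (or coercible) class labels, TRUE = positive.
#' @return A \linkS4class{ROCResult}.
#' @examples
#' r <- rocAnalysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' rocAUC(r)
#' @export
rocAnalysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present for ROC analysis")
  thr <- sort(unique(scores), decreasing = TRUE)
  # counts of scores >= each threshold, per class
  sens <- vapply(thr, function(t) sum(scores >= t & labels), 0) / nPos
  spec <- vapply(thr, function(t) sum(scores < t & !labels), 0) / nNeg
  # curve in (FPR, TPR), padded with the trivial endpoints
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[length(best)]  # thresholds are decreasing: last = lowest
  new("ROCResult", thresholds = thr, sensitivity = sens, specificity = spec,
      auc = auc,
      optimal = c(threshold = thr[best], sensitivity = sens[best],
                  specificity = spec[best]))
}
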
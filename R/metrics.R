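# Multilabel evaluation metrics.
#
# Macro AUC is ranking-based: per label, the fraction of (positive,
# negative) instance pairs whose positive scores at least the negative (ties
# count as successes), averaged over labels that have both positives and
# negatives. The example-based metrics average per-instance terms; the
# F-measure is the harmonic mean of the aggregated precision and recall.
# Zero-denominator conventions: an instance with empty union contributes 1
# to accuracy; an empty prediction contributes 0 to precision; an empty true
# label set contributes 1 to recall (vacuously recovered).

#' Macro (label-wise ranking) AUC
#'
#' @param scores Numeric score matrix, instances x labels.
#' @param Y Binary label matrix of the same shape.
#' @return Mean over includable labels (those with at least one positive and
#'   one negative) of the fraction of positive/negative pairs ranked with
#'   `score(pos) >= score(neg)`; `NA` when no label is includable (with a
#'   warning).
#' @export
macro_auc <- function(scores, Y) {
  scores <- as.matrix(scores); Y <- as.matrix(Y)
  stopifnot(identical(dim(scores), dim(Y)))
  per_label <- vapply(seq_len(ncol(Y)), function(l) {
    pos <- scores[Y[, l] == 1, l]
    neg <- scores[Y[, l] == 0, l]
    if (!length(pos) || !length(neg)) return(NA_real_)
    # pairs with s_pos >= s_neg, counted via the sorted negative scores
    sn <- sort(neg)
    sum(findInterval(pos, sn)) / (length(pos) * length(neg))
  }, numeric(1))
  if (all(is.na(per_label))) {
    warning("macro AUC undefined: no label has both positives and negatives")
    return(NA_real_)
  }
  mean(per_label, na.rm = TRUE)
}

#' Example-based multilabel metrics
#'
#' @param Z Binary prediction matrix.
#' @param Y Binary true-label matrix of the same shape.
#' @return Named vector: `accuracy` (mean Jaccard), `subset_accuracy` (exact
#'   match rate), `precision`, `recall` (per-instance terms averaged) and
#'   `f_measure` (= 2PR/(P+R) on the aggregated P and R).
#' @export
example_based_metrics <- function(Z, Y) {
  Z <- as.matrix(Z); Y <- as.matrix(Y)
  stopifnot(identical(dim(Z), dim(Y)))
  if (!nrow(Y)) stop("example_based_metrics needs at least one instance")
  inter <- rowSums(Z == 1 & Y == 1)
  uni <- rowSums(Z == 1 | Y == 1)
  nz <- rowSums(Z == 1)
  ny <- rowSums(Y == 1)
  acc_terms <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  pre_terms <- ifelse(nz == 0, 0, inter / pmax(nz, 1))
  rec_terms <- ifelse(ny == 0, 1, inter / pmax(ny, 1))
  P <- mean(pre_terms)
  R <- mean(rec_terms)
  c(accuracy = mean(acc_terms),
    subset_accuracy = mean(apply(Z == Y, 1, all)),
    precision = P,
    recall = R,
    f_measure = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

#' Per-AOI prediction accuracy
#'
#' @inheritParams example_based_metrics
#' @return Per-label fraction of instances with `Z_j == Y_j`.
#' @export
per_aoi_accuracy <- function(Z, Y) {
  Z <- as.matrix(Z); Y <- as.matrix(Y)
  stopifnot(identical(dim(Z), dim(Y)))
  setNames(colMeans(Z == Y), paste0("AOI_", seq_len(ncol(Y))))
}
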
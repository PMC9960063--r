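# MLSMOTE: multilabel synthetic minority oversampling.
#
# Labels whose imbalance ratio IRLbl exceeds the mean MeanIR act as seeds:
# every training instance carrying such a label spawns one synthetic
# instance, interpolated between the seed and a random one of its k nearest
# neighbors within the minority bag; the synthetic label vector activates a
# label when it is active in more than half of seed + neighbors. Originals
# are never modified; synthetic rows are appended after them. Applied to
# training folds only — test sets keep their original label distribution.

#' Per-label imbalance profile
#'
#' `IRLbl(l) = max_l' count(l') / count(l)` over labels with at least one
#' positive; `MeanIR` is their mean. Labels with no positives are excluded
#' (they cannot be oversampled).
#'
#' @param Y Binary label matrix.
#' @return List with `IRLbl` (per label, `NA` when the label has no
#'   positives) and `MeanIR`.
#' @export
imbalance_profile <- function(Y) {
  cnt <- colSums(Y)
  irl <- ifelse(cnt > 0, max(cnt) / cnt, NA_real_)
  list(IRLbl = irl, MeanIR = mean(irl, na.rm = TRUE))
}

#' MLSMOTE oversampling
#'
#' @param X Numeric feature matrix (rows align with `Y`).
#' @param Y Binary label matrix.
#' @param k_neighbors Neighborhood size within each minority bag (default 5;
#'   truncated when the bag is smaller).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return List with `X`, `Y` (originals followed by synthetic rows) and
#'   `n_synthetic`.
#' @export
mlsmote <- function(X, Y, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  prof <- imbalance_profile(Y)
  minority <- which(!is.na(prof$IRLbl) & prof$IRLbl > prof$MeanIR)
  binary_col <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  newX <- list()
  newY <- list()
  set.seed(seed)
  for (l in minority) {
    bag <- which(Y[, l] == 1)
    if (length(bag) < 2) {
      warning("MLSMOTE: minority bag for label ", l, " has fewer than 2 instances; skipped")
      next
    }
    k <- min(k_neighbors, length(bag) - 1)
    D <- as.matrix(stats::dist(X[bag, , drop = FALSE]))
    for (bi in seq_along(bag)) {
      ord <- order(D[bi, ], seq_along(bag))
      nb <- setdiff(ord, bi)[seq_len(k)]          # k nearest, ties by index
      ref <- nb[sample.int(k, 1)]
      r <- stats::runif(1)
      seed_x <- X[bag[bi], ]
      ref_x <- X[bag[ref], ]
      synth <- seed_x + r * (ref_x - seed_x)
      synth[binary_col] <- round(synth[binary_col])
      votes <- colSums(Y[bag[c(bi, nb)], , drop = FALSE])
      newX[[length(newX) + 1L]] <- synth
      newY[[length(newY) + 1L]] <- as.integer(votes > (k + 1) / 2)
    }
  }
  if (length(newX)) {
    Xa <- rbind(X, do.call(rbind, newX))
    Ya <- rbind(Y, do.call(rbind, newY))
    rownames(Xa) <- rownames(Ya) <- NULL
  } else {
    Xa <- X; Ya <- Y
  }
  list(X = Xa, Y = Ya, n_synthetic = length(newX))
}
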
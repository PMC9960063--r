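# Discretized mutual information and greedy multilabel feature selection.
#
# Mutual information is computed on discretized feature columns (floor
# approximation by default, matching how the selection scores are defined;
# equal-width binning is offered because flooring pixel-scale features can
# produce huge alphabets) against binary labels, in bits. Multilabel
# relevance of a feature is the sum of its per-label MI. Selection is greedy
# forward with deterministic index tie-breaks.

discretize_column <- function(x, scheme = "floor", bins = 10) {
  if (identical(scheme, "floor")) return(floor(x))
  if (identical(scheme, "equal_width")) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    b <- seq(rng[1], rng[2], length.out = bins + 1)
    return(pmin(findInterval(x, b, rightmost.closed = TRUE), bins))
  }
  stop("unknown discretization scheme: ", scheme)
}

# empirical MI in bits between two discrete vectors
empirical_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Discretized mutual information with a binary label
#'
#' Empirical mutual information (log base 2) between a discretized feature
#' column and a binary label column; satisfies
#' `0 <= I(X;Y) <= min(H(X), H(Y))`.
#'
#' @param x Numeric feature column.
#' @param y Binary label column of the same length.
#' @param scheme `"floor"` (default) or `"equal_width"`.
#' @param bins Number of bins for `equal_width`.
#' @return MI in bits (0 for a constant column).
#' @export
discretized_mi <- function(x, y, scheme = "floor", bins = 10) {
  stopifnot(length(x) == length(y))
  xd <- discretize_column(x, scheme, bins)
  if (length(unique(xd)) < 2 || length(unique(y)) < 2) return(0)
  max(empirical_mi(xd, y), 0)
}

# joint MI of a feature pair with a label: I((x1, x2); y)
joint_mi <- function(x1, x2, y, scheme = "floor", bins = 10) {
  j <- interaction(discretize_column(x1, scheme, bins),
                   discretize_column(x2, scheme, bins), drop = TRUE)
  if (length(unique(j)) < 2 || length(unique(y)) < 2) return(0)
  max(empirical_mi(j, y), 0)
}

fisher_score <- function(x, y) {
  x1 <- x[y == 1]; x0 <- x[y == 0]
  if (!length(x1) || !length(x0)) return(0)
  v1 <- if (length(x1) > 1) stats::var(x1) else 0
  v0 <- if (length(x0) > 1) stats::var(x0) else 0
  (mean(x1) - mean(x0))^2 / (v1 + v0 + 1e-12)
}

#' Multilabel feature selection
#'
#' Greedy forward ranking of feature columns against a multilabel target.
#' Methods:
#' * `MLMIM`: by multilabel relevance (sum over labels of discretized MI);
#' * `MLMRMR`: relevance minus the mean MI with already-selected features;
#' * `MLJMI`: mean over selected features of the joint MI of (candidate,
#'   selected) with the labels (summed over labels);
#' * `FSCORE`: sum over labels of the per-label Fisher score.
#'
#' `MIFS` and `RFS` are accepted as names but not implemented. Ties are
#' broken by feature index; the ranking is deterministic.
#'
#' @param X Numeric feature matrix.
#' @param Y Binary label matrix.
#' @param method One of `"MLMIM"`, `"MLJMI"`, `"MLMRMR"`, `"FSCORE"`.
#' @param n_features Number of features to rank (<= ncol(X)).
#' @param scheme,bins Discretization passed to [discretized_mi()].
#' @return List with `selected` (ordered column indices), `scores` (the
#'   greedy criterion value at each pick), `relevance` (per-feature
#'   multilabel relevance) and `method`.
#' @export
select_features <- function(X, Y, method = "MLMIM", n_features = 10,
                            scheme = "floor", bins = 10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X)
  stopifnot(n_features <= p, nrow(X) == nrow(Y))
  method <- toupper(method)
  if (method %in% c("MIFS", "RFS")) {
    stop("feature selection method ", method,
         " is not implemented (pluggable name only)")
  }
  if (!method %in% c("MLMIM", "MLJMI", "MLMRMR", "FSCORE")) {
    stop("unknown feature selection method: ", method)
  }
  labels <- seq_len(ncol(Y))
  if (method == "FSCORE") {
    rel <- vapply(seq_len(p), function(f)
      sum(vapply(labels, function(l) fisher_score(X[, f], Y[, l]), numeric(1))),
      numeric(1))
    ord <- order(-rel, seq_len(p))[seq_len(n_features)]
    return(list(selected = ord, scores = rel[ord], relevance = rel,
                method = method))
  }
  rel <- vapply(seq_len(p), function(f)
    sum(vapply(labels, function(l)
      discretized_mi(X[, f], Y[, l], scheme, bins), numeric(1))),
    numeric(1))
  if (method == "MLMIM") {
    ord <- order(-rel, seq_len(p))[seq_len(n_features)]
    return(list(selected = ord, scores = rel[ord], relevance = rel,
                method = method))
  }
  selected <- integer(0)
  scores <- numeric(0)
  # pairwise feature-feature MI cache for MLMRMR
  ffmi <- function(f, s) discretized_mi(X[, f], discretize_column(X[, s], scheme, bins),
                                        scheme, bins)
  while (length(selected) < n_features) {
    cand <- setdiff(seq_len(p), selected)
    crit <- vapply(cand, function(f) {
      if (!length(selected)) return(rel[f])
      if (method == "MLMRMR") {
        red <- mean(vapply(selected, function(s) ffmi(f, s), numeric(1)))
        rel[f] - red
      } else { # MLJMI
        mean(vapply(selected, function(s)
          sum(vapply(labels, function(l)
            joint_mi(X[, f], X[, s], Y[, l], scheme, bins), numeric(1))),
          numeric(1)))
      }
    }, numeric(1))
    pick <- cand[order(-crit, cand)[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[match(pick, cand)])
  }
  list(selected = selected, scores = scores, relevance = rel, method = method)
}

#' Write a selection report as JSON
#'
#' Persists the method, per-feature relevance scores and chosen order —
#' enough to regenerate an MI-per-selected-feature chart.
#'
#' @param selection A [select_features()] result.
#' @param feature_names Column names of the feature matrix.
#' @param path Output JSON path.
#' @export
write_selection_report <- function(selection, feature_names, path) {
  jsonlite::write_json(list(
    method = selection$method,
    selected = feature_names[selection$selected],
    scores = selection$scores,
    relevance = setNames(as.list(selection$relevance), feature_names)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
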
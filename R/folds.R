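# Window-balanced user -> fold assignment.
#
# Cross-validation folds partition users (never windows), and users browse
# for different lengths of time, so fold sizes are balanced on the total
# number of windows each user contributes. The assignment minimizes
# sum_k |x_k - xbar| over all ways of giving each user to exactly one fold,
# where x_k is the window total of fold k and xbar their mean. The absolute
# deviations are the linearization variables U_k >= x_k - xbar,
# U_k >= -(x_k - xbar) of the integer program; the optimum is found by an
# exact branch-and-bound (compiled), cross-checked by exhaustive enumeration
# on small instances.

#' Assign users to folds, balancing window counts
#'
#' @param P Named numeric vector of per-user window counts (windows summed
#'   over all of a user's recordings).
#' @param K Number of folds (default 10).
#' @param node_cap Search-node budget for the branch-and-bound; exceeded only
#'   on adversarial instances, in which case the best incumbent is returned
#'   with a warning and `optimal = FALSE`.
#' @return An object of class `fold_assignment`: list with `fold` (named
#'   integer vector, 1..K per user), `x` (per-fold window totals), `xbar`,
#'   `objective` (= sum |x_k - xbar|), `optimal`.
#' @export
assign_folds <- function(P, K = 10, node_cap = 5e7) {
  stopifnot(is.numeric(P), all(P >= 0), K >= 2)
  N <- length(P)
  if (K > N) stop("infeasible: more folds (", K, ") than users (", N, ")")
  if (any(P != round(P))) stop("window counts must be integers")
  res <- fold_partition_bb(as.numeric(P), as.integer(K), node_cap)
  if (!res$optimal) {
    warning("fold assignment search hit the node cap; returning best incumbent")
  }
  fold <- res$fold
  names(fold) <- if (!is.null(names(P))) names(P) else as.character(seq_len(N))
  structure(list(
    fold = fold,
    x = res$x,
    xbar = sum(P) / K,
    objective = res$objective,
    optimal = res$optimal,
    K = as.integer(K)
  ), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d users -> %d folds; window totals [%s], objective %.3f%s\n",
              length(x$fold), x$K, paste(x$x, collapse = ", "), x$objective,
              if (x$optimal) "" else " (incumbent, not proven optimal)"))
  invisible(x)
}

#' Exhaustive fold-assignment oracle
#'
#' Brute-force minimum of `sum_k |x_k - xbar|` over all `K^N` assignments;
#' independent check for [assign_folds()] on small instances.
#'
#' @param P Per-user window counts.
#' @param K Number of folds.
#' @param cap Maximum number of assignments to enumerate (default `3^10`).
#' @return List with `objective` and one optimal `fold` vector.
#' @export
enumerate_folds_oracle <- function(P, K, cap = 3^10) {
  N <- length(P)
  if (K^N > cap) stop("enumeration cap exceeded: K^N = ", K^N, " > ", cap)
  xbar <- sum(P) / K
  best <- Inf
  best_assign <- NULL
  assign <- integer(N)
  total <- K^N
  for (code in 0:(total - 1)) {
    c0 <- code
    for (u in seq_len(N)) {
      assign[u] <- c0 %% K + 1
      c0 <- c0 %/% K
    }
    x <- vapply(seq_len(K), function(k) sum(P[assign == k]), numeric(1))
    obj <- sum(abs(x - xbar))
    if (obj < best) {
      best <- obj
      best_assign <- assign
    }
  }
  list(objective = best, fold = best_assign)
}
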
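# Multilabel classifiers: binary relevance (BR) and classifier chains (CC)
# over ridge-regression, kNN and linear-SVM bases, plus ML-kNN.
#
# Features are standardized with training-fold statistics before fitting;
# the same constants are applied at prediction time. Scores are the base
# model's ranking output (ridge: raw linear output; kNN: positive-neighbor
# fraction; SVM: decision value; ML-kNN: Bayesian posterior); hard
# predictions threshold the score (0.5 for ridge/kNN/ML-kNN, 0 for SVM
# decision values), with the >= convention at the boundary.

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")
}

# ---- base learners -------------------------------------------------------

fit_base <- function(X, y, base, params) {
  if (length(unique(y)) < 2) {
    warning("constant label column; base degenerates to a constant scorer")
    return(list(kind = "constant", value = y[1],
                threshold = if (base == "svm") 0 else 0.5))
  }
  switch(base,
    ridge = {
      lambda <- params$lambda %||% 1
      intercept <- params$intercept %||% TRUE
      Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
      pen <- diag(rep(lambda, ncol(Xd)))
      if (intercept) pen[1, 1] <- 0           # intercept unpenalized
      beta <- solve(crossprod(Xd) + pen, crossprod(Xd, y))
      list(kind = "ridge", beta = drop(beta), intercept = intercept,
           threshold = 0.5)
    },
    knn = {
      list(kind = "knn", K = params$K %||% 20, X = X, y = y, threshold = 0.5)
    },
    svm = {
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                        cost = params$C %||% 1, scale = FALSE)
      # orient decision values so larger = more likely label 1
      dv <- attr(stats::predict(fit, X[1:2, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      flip <- grepl("^0/1", colnames(dv))
      list(kind = "svm", fit = fit, flip = flip, threshold = 0)
    },
    stop("unknown base learner: ", base))
}

score_base <- function(model, X) {
  switch(model$kind,
    constant = rep(as.numeric(model$value), nrow(X)),
    ridge = {
      Xd <- if (model$intercept) cbind(1, X) else X
      drop(Xd %*% model$beta)
    },
    knn = {
      knn_scores(model$X, model$y, X, model$K)
    },
    svm = {
      dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                 "decision.values")
      if (model$flip) -drop(dv) else drop(dv)
    })
}

# fraction of the K nearest training points (Euclidean; ties in the K-th
# distance broken by lower training index) that carry the label
knn_scores <- function(Xtr, y, Xq, K) {
  if (!nrow(Xq)) return(numeric(0))
  K <- min(K, nrow(Xtr))
  # squared Euclidean cross-distances
  d2 <- outer(rowSums(Xq^2), rowSums(Xtr^2), "+") - 2 * Xq %*% t(Xtr)
  vapply(seq_len(nrow(Xq)), function(i) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(K)]
    mean(y[nb])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- multilabel wrappers -------------------------------------------------

#' Fit a binary-relevance multilabel model
#'
#' One independent base model per label.
#'
#' @param X Numeric feature matrix.
#' @param Y Binary label matrix.
#' @param base `"ridge"`, `"knn"` or `"svm"`.
#' @param params Base parameters: `lambda` (+ optional `intercept`) for
#'   ridge, `K` for knn, `C` for svm.
#' @param standardize Standardize features with training statistics
#'   (default TRUE).
#' @return A `multilabel_model`.
#' @export
fit_binary_relevance <- function(X, Y, base = "knn", params = list(),
                                 standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  st <- if (standardize) standardize_fit(X) else NULL
  Xs <- if (is.null(st)) X else standardize_apply(X, st)
  models <- lapply(seq_len(ncol(Y)), function(l) fit_base(Xs, Y[, l], base, params))
  structure(list(strategy = "BR", base = base, params = params,
                 models = models, standardize = st,
                 registry = colnames(X), n_labels = ncol(Y)),
            class = "multilabel_model")
}

#' Fit a classifier-chain multilabel model
#'
#' Label `order[i]`'s base model is trained on the features augmented with
#' the true labels earlier in the chain; prediction feeds hard predicted
#' labels forward in the same order.
#'
#' @inheritParams fit_binary_relevance
#' @param order Permutation of label indices (default 1..n, AOI order).
#' @return A `multilabel_model`.
#' @export
fit_classifier_chain <- function(X, Y, base = "knn", params = list(),
                                 order = seq_len(ncol(Y)), standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(order) != ncol(Y) || !all(sort(order) == seq_len(ncol(Y)))) {
    stop("order must be a permutation of 1..", ncol(Y))
  }
  st <- if (standardize) standardize_fit(X) else NULL
  Xs <- if (is.null(st)) X else standardize_apply(X, st)
  models <- vector("list", ncol(Y))
  aug <- Xs
  for (i in seq_along(order)) {
    l <- order[i]
    models[[i]] <- fit_base(aug, Y[, l], base, params)
    aug <- cbind(aug, Y[, l])
  }
  structure(list(strategy = "CC", base = base, params = params,
                 models = models, order = order, standardize = st,
                 registry = colnames(X), n_labels = ncol(Y)),
            class = "multilabel_model")
}

#' Fit an ML-kNN model
#'
#' Standard ML-kNN: per-label priors with Laplace smoothing `s`, and
#' likelihoods of observing `c = 0..k` positive neighbors, estimated from the
#' training set's own k-neighborhoods (self excluded); the score of a query
#' is the smoothed posterior probability of the label given its positive
#' neighbor count.
#'
#' @param X Numeric feature matrix.
#' @param Y Binary label matrix.
#' @param k Neighborhood size (default 15).
#' @param s Laplace smoothing constant (default 1).
#' @param standardize Standardize features (default TRUE).
#' @return A `multilabel_model`.
#' @export
fit_mlknn <- function(X, Y, k = 15, s = 1, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X)
  if (k >= m) stop("ML-kNN requires k < number of training instances")
  st <- if (standardize) standardize_fit(X) else NULL
  Xs <- if (is.null(st)) X else standardize_apply(X, st)
  prior1 <- (s + colSums(Y)) / (2 * s + m)
  # neighbor label counts for each training instance (self excluded)
  d2 <- as.matrix(stats::dist(Xs))^2
  diag(d2) <- Inf
  counts <- t(vapply(seq_len(m), function(i) {
    nb <- order(d2[i, ], seq_len(m))[seq_len(k)]
    colSums(Y[nb, , drop = FALSE])
  }, numeric(ncol(Y))))
  # likelihood tables: P(c positives among k | label on/off)
  lik1 <- lik0 <- matrix(0, nrow = k + 1, ncol = ncol(Y))
  for (l in seq_len(ncol(Y))) {
    on <- Y[, l] == 1
    c1 <- tabulate(counts[on, l] + 1, nbins = k + 1)
    c0 <- tabulate(counts[!on, l] + 1, nbins = k + 1)
    lik1[, l] <- (s + c1) / (s * (k + 1) + sum(c1))
    lik0[, l] <- (s + c0) / (s * (k + 1) + sum(c0))
  }
  structure(list(strategy = "MLKNN", base = "mlknn",
                 params = list(k = k, s = s),
                 X = Xs, Y = Y, k = k, prior1 = prior1,
                 lik1 = lik1, lik0 = lik0, standardize = st,
                 registry = colnames(X), n_labels = ncol(Y)),
            class = "multilabel_model")
}

#' Score a multilabel model
#'
#' Returns the per-label ranking scores: raw linear output (ridge),
#' positive-neighbor fraction (kNN), decision value (SVM) or posterior
#' probability (ML-kNN). Classifier chains feed hard chained predictions
#' forward before scoring each label.
#'
#' @param model A `multilabel_model`.
#' @param X Feature matrix with the training registry's columns.
#' @return Numeric score matrix, instances x labels.
#' @export
score <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$registry) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$registry)) {
    stop("feature registry mismatch between model and prediction input")
  }
  if (!nrow(X)) return(matrix(numeric(0), 0, model$n_labels))
  Xs <- if (is.null(model$standardize)) X else standardize_apply(X, model$standardize)
  if (model$strategy == "BR") {
    S <- vapply(model$models, function(mdl) score_base(mdl, Xs),
                numeric(nrow(Xs)))
    return(matrix(S, nrow = nrow(Xs)))
  }
  if (model$strategy == "CC") {
    S <- matrix(NA_real_, nrow(Xs), model$n_labels)
    aug <- Xs
    for (i in seq_along(model$order)) {
      l <- model$order[i]
      sc <- score_base(model$models[[i]], aug)
      S[, l] <- sc
      hard <- as.numeric(sc >= model$models[[i]]$threshold)
      aug <- cbind(aug, hard)
    }
    return(S)
  }
  # ML-kNN
  m <- nrow(model$X)
  d2 <- outer(rowSums(Xs^2), rowSums(model$X^2), "+") - 2 * Xs %*% t(model$X)
  S <- matrix(NA_real_, nrow(Xs), model$n_labels)
  for (i in seq_len(nrow(Xs))) {
    nb <- order(d2[i, ], seq_len(m))[seq_len(model$k)]
    cs <- colSums(model$Y[nb, , drop = FALSE])
    for (l in seq_len(model$n_labels)) {
      p1 <- model$prior1[l] * model$lik1[cs[l] + 1, l]
      p0 <- (1 - model$prior1[l]) * model$lik0[cs[l] + 1, l]
      S[i, l] <- p1 / (p1 + p0)
    }
  }
  S
}

#' @rdname score
#' @param threshold Decision threshold; `NULL` uses each base's convention
#'   (0.5, or 0 for SVM decision values). Prediction uses `score >=
#'   threshold`.
#' @return `predict_labels()` returns a binary matrix.
#' @export
predict_labels <- function(model, X, threshold = NULL) {
  S <- score(model, X)
  if (!nrow(S)) return(matrix(integer(0), 0, model$n_labels))
  th <- if (!is.null(threshold)) rep(threshold, model$n_labels)
        else if (model$strategy == "MLKNN") rep(0.5, model$n_labels)
        else vapply(model$models, `[[`, numeric(1), "threshold")
  if (model$strategy == "CC") th <- th[base::order(model$order)]
  Z <- matrix(0L, nrow(S), ncol(S))
  for (l in seq_len(ncol(S))) Z[, l] <- as.integer(S[, l] >= th[l])
  Z
}

#' @export
print.multilabel_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("<multilabel_model> %s-%s (%s), %d labels, %d features\n",
              x$base, x$strategy,
              paste(names(p), unlist(p), sep = "=", collapse = ", "),
              x$n_labels, length(x$registry)))
  invisible(x)
}
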
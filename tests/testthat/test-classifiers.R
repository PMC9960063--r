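test_that("ridge base reproduces its closed form", {
  # lambda = 1, no intercept, X = [1, 2], y = [1, 2]: beta = 5/6
  X <- matrix(c(1, 2), ncol = 1)
  m <- fit_binary_relevance(X, cbind(c(1, 2)), base = "ridge",
                            params = list(lambda = 1, intercept = FALSE),
                            standardize = FALSE)
  expect_equal(unname(m$models[[1]]$beta), 5 / 6, tolerance = 1e-12)
  expect_equal(drop(score(m, matrix(3))), 2.5, tolerance = 1e-12)

  # lambda -> 0 limit recovers an exact linear relation
  set.seed(3)
  X2 <- cbind(rnorm(30), rnorm(30))
  y2 <- drop(X2 %*% c(2, -1)) + 0.5
  m2 <- fit_binary_relevance(X2, cbind(y2), "ridge",
                             params = list(lambda = 1e-10), standardize = FALSE)
  expect_equal(drop(score(m2, X2)), y2, tolerance = 1e-6)

  # lambda -> Inf drives scores to the training label mean
  m3 <- fit_binary_relevance(X2, cbind(y2), "ridge",
                             params = list(lambda = 1e10), standardize = FALSE)
  expect_equal(drop(score(m3, X2)), rep(mean(y2), 30), tolerance = 1e-4)
})

test_that("ridge scores are monotone in a positively weighted feature", {
  set.seed(4)
  X <- cbind(runif(40), runif(40))
  y <- as.integer(X[, 1] > 0.5)
  m <- fit_binary_relevance(X, cbind(y), "ridge", params = list(lambda = 0.5),
                            standardize = FALSE)
  b1 <- m$models[[1]]$beta[2]
  expect_gt(b1, 0)
  s_lo <- drop(score(m, matrix(c(0.2, 0.5), 1)))
  s_hi <- drop(score(m, matrix(c(0.9, 0.5), 1)))
  expect_gt(s_hi, s_lo)
})

test_that("kNN base scores the positive-neighbor fraction with tie-breaks", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  Y <- cbind(c(1, 1, 0, 0))
  m <- fit_binary_relevance(X, Y, "knn", params = list(K = 1),
                            standardize = FALSE)
  expect_equal(drop(score(m, matrix(1))), 1)   # query equals training point
  m4 <- fit_binary_relevance(X, Y, "knn", params = list(K = 4),
                             standardize = FALSE)
  expect_equal(drop(score(m4, matrix(1.5))), 0.5)
  # score 0.5 -> predicted 1 at threshold 0.5 (>= convention)
  expect_equal(drop(predict_labels(m4, matrix(1.5))), 1L)
  # equidistant neighbors: lower training index wins
  m1 <- fit_binary_relevance(X, Y, "knn", params = list(K = 2),
                             standardize = FALSE)
  expect_equal(drop(score(m1, matrix(2.5))), 0)  # picks rows 3 and 4
  # empty query
  expect_equal(nrow(score(m1, X[0, , drop = FALSE])), 0)
})

test_that("binary relevance isolates labels; classifier chains feed them forward", {
  set.seed(6)
  X <- matrix(rnorm(120), 60, 2)
  y1 <- as.integer(X[, 1] > 0)
  Y <- cbind(y1, as.integer(X[, 2] > 0))
  m <- fit_binary_relevance(X, Y, "knn", params = list(K = 5))
  # permuting the *other* label column leaves label 1's model untouched
  Yperm <- cbind(y1, sample(Y[, 2]))
  mperm <- fit_binary_relevance(X, Yperm, "knn", params = list(K = 5))
  q <- matrix(rnorm(10), 5, 2)
  expect_equal(score(m, q)[, 1], score(mperm, q)[, 1])

  # label 2 identical to label 1: a chain in order (1, 2) predicts it
  # perfectly from the chained input
  Ydep <- cbind(y1, y1)
  cc <- fit_classifier_chain(X, Ydep, "knn", params = list(K = 3),
                             order = c(1, 2))
  Z <- predict_labels(cc, X)
  expect_equal(Z[, 2], Z[, 1])

  # labels independent given X: CC scores match BR scores
  br <- fit_binary_relevance(X, Y, "ridge", params = list(lambda = 1))
  ccr <- fit_classifier_chain(X, Y, "ridge", params = list(lambda = 1))
  expect_equal(score(br, q)[, 1], score(ccr, q)[, 1], tolerance = 1e-10)
  expect_error(fit_classifier_chain(X, Y, "knn", list(K = 3), order = c(1, 1)),
               "permutation")
})

test_that("constant label columns degrade to constant scorers with a warning", {
  X <- matrix(rnorm(20), 10, 2)
  Y <- cbind(rep(1L, 10), rep(0:1, 5))
  expect_warning(m <- fit_binary_relevance(X, Y, "knn", list(K = 3)),
                 "constant label")
  expect_equal(score(m, X)[, 1], rep(1, 10))
})

test_that("ML-kNN matches a direct Bayes-rule computation", {
  set.seed(10)
  X <- matrix(rnorm(24), 12, 2)
  Y <- cbind(as.integer(X[, 1] > 0), as.integer(X[, 2] > -0.5))
  k <- 3; s <- 1
  m <- fit_mlknn(X, Y, k = k, s = s, standardize = FALSE)
  # independent oracle: literal ML-kNN tables from pairwise distances
  D <- as.matrix(dist(X)); diag(D) <- Inf
  cnt <- t(sapply(1:12, function(i)
    colSums(Y[order(D[i, ])[1:k], , drop = FALSE])))
  q <- matrix(c(0.3, 0.1), 1)
  dq <- sqrt(colSums((t(X) - drop(q))^2))
  nb <- order(dq)[1:k]
  cq <- colSums(Y[nb, , drop = FALSE])
  for (l in 1:2) {
    prior1 <- (s + sum(Y[, l])) / (2 * s + 12)
    kj1 <- sapply(0:k, function(c) sum(cnt[Y[, l] == 1, l] == c))
    kj0 <- sapply(0:k, function(c) sum(cnt[Y[, l] == 0, l] == c))
    p1 <- prior1 * (s + kj1[cq[l] + 1]) / (s * (k + 1) + sum(kj1))
    p0 <- (1 - prior1) * (s + kj0[cq[l] + 1]) / (s * (k + 1) + sum(kj0))
    expect_equal(score(m, q)[1, l], p1 / (p1 + p0), tolerance = 1e-12)
  }
  # smoothing floor: a label with no positives keeps a nonzero prior
  Y0 <- cbind(Y[, 1], rep(0L, 12))
  m0 <- fit_mlknn(X, Y0, k = 3)
  expect_equal(m0$prior1[2], 1 / 14)
  expect_true(all(score(m0, X) >= 0 & score(m0, X) <= 1))
  # all-active label predicts active everywhere
  Y1 <- cbind(Y[, 1], rep(1L, 12))
  m1 <- fit_mlknn(X, Y1, k = 3)
  expect_true(all(predict_labels(m1, matrix(rnorm(6), 3))[, 2] == 1))
  expect_error(fit_mlknn(X, Y, k = 12), "k <")
})

test_that("SVM base wraps a linear margin classifier inside BR", {
  set.seed(12)
  X <- matrix(rnorm(100), 50, 2)
  Y <- cbind(as.integer(X[, 1] + 0.3 * X[, 2] > 0),
             as.integer(X[, 2] < 0.2))
  m <- fit_binary_relevance(X, Y, "svm", params = list(C = 1))
  Z <- predict_labels(m, X)
  expect_gt(mean(Z[, 1] == Y[, 1]), 0.9)
  S <- score(m, X)
  # decision values rank positives above negatives
  expect_gt(suppressWarnings(macro_auc(S, Y)), 0.9)
})

test_that("fits are deterministic and reject registry mismatches", {
  set.seed(14)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  Y <- cbind(as.integer(X[, 1] > 0), as.integer(X[, 2] > 0))
  m1 <- fit_binary_relevance(X, Y, "knn", list(K = 3))
  m2 <- fit_binary_relevance(X, Y, "knn", list(K = 3))
  expect_identical(score(m1, X), score(m2, X))
  Xbad <- X; colnames(Xbad) <- c("b", "a")
  expect_error(score(m1, Xbad), "registry")
})
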
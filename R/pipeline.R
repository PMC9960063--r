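# Experiment orchestration.
#
# One experiment: filter fixations, segment recordings into tau-windows,
# assign users to window-balanced folds, then per fold build labels and
# features (population Heat from training users only), balance the training
# set with MLSMOTE, rank features on the training set, fit the multilabel
# model, score the held-out fold and evaluate. Metrics are averaged over
# folds with their standard deviation, and the per-window classification
# time (scoring wall time / test windows) is recorded for the online-
# feasibility report.

#' Model configuration
#'
#' @param strategy `"BR"`, `"CC"` or `"MLKNN"`.
#' @param base `"ridge"`, `"knn"` or `"svm"` (ignored for ML-kNN).
#' @param params Base parameters (`lambda`, `K`, `C`, `k`).
#' @param selection Feature-selection method (`"MLMIM"`, `"MLJMI"`,
#'   `"MLMRMR"`, `"FSCORE"`).
#' @param n_features Number of features to select.
#' @param label Display label; derived from the settings when omitted.
#' @return A `model_config` list.
#' @export
model_config <- function(strategy = "BR", base = "knn",
                         params = list(K = 20), selection = "MLMIM",
                         n_features = 10, label = NULL) {
  if (is.null(label)) {
    label <- if (strategy == "MLKNN") "ML-KNN"
             else paste0(toupper(substr(base, 1, 1)),
                         if (base == "ridge") "R" else toupper(substring(base, 2)),
                         "-", strategy)
    label <- switch(paste(strategy, base),
                    "BR knn" = "KNN-BR", "CC knn" = "KNN-CC",
                    "BR ridge" = "RR-BR", "CC ridge" = "RR-CC",
                    "BR svm" = "SVM-BR", "CC svm" = "SVM-CC",
                    label)
  }
  structure(list(strategy = strategy, base = base, params = params,
                 selection = selection, n_features = n_features,
                 label = label), class = "model_config")
}

#' The reference configuration
#'
#' KNN binary relevance with K = 20 neighbors and 10 features ranked by
#' MLMIM — the configuration that maximizes accuracy and subset accuracy on
#' the study data.
#'
#' @return A [model_config()].
#' @export
best_model_config <- function() {
  model_config("BR", "knn", list(K = 20), "MLMIM", 10, label = "KNN-BR")
}

fit_config <- function(cfg, X, Y, seed) {
  switch(cfg$strategy,
    BR = fit_binary_relevance(X, Y, cfg$base, cfg$params),
    CC = fit_classifier_chain(X, Y, cfg$base, cfg$params),
    MLKNN = fit_mlknn(X, Y, k = cfg$params$k %||% 15),
    stop("unknown strategy: ", cfg$strategy))
}

#' Run a cross-validated visit-intention experiment
#'
#' @param recordings List of `gaze_recording`s (fixations may be unfiltered;
#'   the < 100 ms filter is applied here).
#' @param layout An `aoi_layout`.
#' @param configs List of [model_config()]s (default: the best
#'   configuration).
#' @param tau_s Window length in seconds (default 5).
#' @param K Number of folds (default 10).
#' @param seed Integer seed driving MLSMOTE.
#' @param balance Apply MLSMOTE to training folds (default TRUE).
#' @return An `eval_report`: list with `summary` (per-config mean and sd of
#'   AUC, subset accuracy, F-measure, accuracy, precision, recall, per-AOI
#'   accuracy, per-window classification time in s), `per_fold`, `mc`
#'   (majority-class baselines), `folds` (the assignment), and `selected`
#'   (per-config, per-fold selected feature names).
#' @export
run_experiment <- function(recordings, layout, configs = list(best_model_config()),
                           tau_s = 5, K = 10, seed = 1, balance = TRUE) {
  if (!length(recordings)) stop("run_experiment: no recordings")
  recordings <- lapply(recordings, function(r)
    set_fixations(r, filter_short_fixations(r$fixations), source = r$fixation_source))
  extracted <- lapply(recordings, extract_features, layout = layout, tau_s = tau_s)
  users <- vapply(recordings, `[[`, character(1), "user_id")
  P <- tapply(vapply(extracted, function(e) nrow(e$labels), integer(1)),
              users, sum)
  folds <- assign_folds(P[unique(users)], K)
  mc <- majority_class_ratio(lapply(extracted, `[[`, "labels"))

  per_fold <- list()
  selected_names <- list()
  for (k in seq_len(K)) {
    dm <- build_design_matrix(recordings, layout, tau_s, folds, k,
                              extracted = extracted)
    if (!nrow(dm$train$X) || !nrow(dm$test$X)) next
    tr <- dm$train
    if (balance) {
      bal <- mlsmote(tr$X, tr$Y, seed = derive_seed(seed, k))
      trX <- bal$X; trY <- bal$Y
    } else {
      trX <- tr$X; trY <- tr$Y
    }
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      sel <- select_features(trX, trY, cfg$selection, cfg$n_features,
                             scheme = "equal_width")
      Xtr <- trX[, sel$selected, drop = FALSE]
      Xte <- dm$test$X[, sel$selected, drop = FALSE]
      model <- fit_config(cfg, Xtr, trY, seed)
      t0 <- proc.time()[["elapsed"]]
      S <- score(model, Xte)
      elapsed <- proc.time()[["elapsed"]] - t0
      Z <- predict_labels(model, Xte)
      ex <- example_based_metrics(Z, dm$test$Y)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        config = cfg$label, fold = k,
        auc = suppressWarnings(macro_auc(S, dm$test$Y)),
        subset_accuracy = ex[["subset_accuracy"]],
        f_measure = ex[["f_measure"]],
        accuracy = ex[["accuracy"]],
        precision = ex[["precision"]],
        recall = ex[["recall"]],
        t(per_aoi_accuracy(Z, dm$test$Y)),
        time_per_window_s = elapsed / nrow(Xte),
        n_test = nrow(Xte))
      selected_names[[cfg$label]] <- c(selected_names[[cfg$label]],
                                       list(dm$registry[sel$selected]))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- setdiff(names(per_fold), c("config", "fold", "n_test"))
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$config), function(d) {
    means <- colMeans(d[metrics], na.rm = TRUE)
    sds <- vapply(d[metrics], stats::sd, numeric(1), na.rm = TRUE)
    out <- data.frame(config = d$config[1], t(means))
    names(out)[-1] <- metrics
    for (m in metrics) out[[paste0(m, "_sd")]] <- sds[[m]]
    out
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, per_fold = per_fold, mc = mc,
                 folds = folds, selected = selected_names,
                 tau_s = tau_s, K = K, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> tau = %g s, %d folds\n", x$tau_s, x$K))
  cols <- c("config", "auc", "subset_accuracy", "f_measure", "accuracy",
            "precision")
  print(format(x$summary[cols], digits = 3), row.names = FALSE)
  invisible(x)
}

#' Window-length sensitivity analysis
#'
#' Reruns the full experiment for each window length and stacks the
#' summaries (a metrics-by-tau table) together with the per-window
#' classification times per tau.
#'
#' @inheritParams run_experiment
#' @param taus Window lengths in seconds (default `c(3, 5, 10, 15, 20)`).
#' @return List with `metrics` (config x tau summary rows), `timing`
#'   (config x tau mean/sd per-window scoring time) and `reports` (the
#'   per-tau `eval_report`s).
#' @export
sensitivity_analysis <- function(recordings, layout,
                                 configs = list(best_model_config()),
                                 taus = c(3, 5, 10, 15, 20), K = 10,
                                 seed = 1, balance = TRUE) {
  reports <- lapply(taus, function(tau)
    run_experiment(recordings, layout, configs, tau_s = tau, K = K,
                   seed = seed, balance = balance))
  names(reports) <- as.character(taus)
  metrics <- do.call(rbind, lapply(seq_along(taus), function(i) {
    s <- reports[[i]]$summary
    cbind(tau_s = taus[i], s)
  }))
  timing <- do.call(rbind, lapply(seq_along(taus), function(i) {
    pf <- reports[[i]]$per_fold
    do.call(rbind, lapply(split(pf, pf$config), function(d)
      data.frame(tau_s = taus[i], config = d$config[1],
                 time_per_window_s = mean(d$time_per_window_s),
                 time_per_window_sd = stats::sd(d$time_per_window_s))))
  }))
  rownames(metrics) <- rownames(timing) <- NULL
  list(metrics = metrics, timing = timing, reports = reports)
}
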
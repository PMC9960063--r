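# Window-instance features.
#
# Three families are computed for every prediction instance (user, session,
# window t >= 2; window 1 is dropped because every family needs window t-1):
#
#  * visit-history features over AOIs and components: time since last visit,
#    recent-window activation flags (r1..r3), where the previous window ended,
#    per-component visit averages, and the population-level Heat_AOI;
#  * gaze kinematics of the previous window: last position, mean/sd of
#    position, velocity and acceleration in X and Y (central differences);
#  * oculomotor statistics over the whole history before the window: counts
#    and duration/amplitude summaries of fixations and saccades.
#
# Causality: every feature of instance (u, t) depends only on data of user u
# before To(t), plus (for Heat_AOI) training-fold users' labels. All
# unobserved quantities fall back to 0.

#' Feature-name registry for a layout
#'
#' Stable column order for the design matrix: AOI history features, component
#' history features, kinematics, oculomotor statistics, then the
#' population-level `Heat_AOI_j` columns (filled per training fold).
#'
#' @param layout An `aoi_layout`.
#' @return Character vector of feature names.
#' @export
feature_registry <- function(layout) {
  n <- layout$n_aoi
  comps <- layout$components$id
  aoi_f <- c(t(outer(paste0("AOI_", seq_len(n)),
                     c("_tslv", "_r1", "_r2", "_r3", "_end_r1"), paste0)))
  comp_f <- c(t(outer(comps, c("_his", "_end_r1", "_tslv", "_atv", "_atbv"),
                      paste0)))
  kin <- c("coord", "Mean", "Std", "Vel", "MeanVel", "StdVel",
           "Acl", "MeanAcl", "StdAcl")
  c(aoi_f, "End_r1", comp_f, "Comp_end",
    paste0(kin, "X"), paste0(kin, "Y"),
    "NFix", "TPromFix", "TMaxFix", "TMinFix",
    "NSac", "APromSac", "AMaxSac", "AMinSac",
    paste0("Heat_AOI_", seq_len(n)))
}

#' AOI visit-history features for one window
#'
#' @param labels Binary label matrix of the recording (windows x AOIs).
#' @param hits [fixation_hits()] table of the recording.
#' @param t Window index (>= 1).
#' @param tau_s Window length in seconds.
#' @return Named vector: `AOI_j_tslv` (s), `AOI_j_r1/r2/r3`, `AOI_j_end_r1`
#'   and `End_r1`.
#' @export
aoi_history_features <- function(labels, hits, t, tau_s) {
  n <- ncol(labels)
  To <- (t - 1) * tau_s * 1000
  out <- numeric(0)
  end_aoi <- last_fixation_aoi_in_window(hits, t - 1L, tau_s)
  for (j in seq_len(n)) {
    past <- hits[!is.na(hits$aoi) & hits$aoi == j & hits$onset_ms < To, , drop = FALSE]
    tslv <- if (nrow(past)) (To - min(max(past$offset_ms), To)) / 1000 else 0
    r <- vapply(1:3, function(q) if (t - q >= 1) labels[t - q, j] else 0, numeric(1))
    out <- c(out, setNames(c(tslv, r, as.numeric(identical(end_aoi, j))),
                           paste0("AOI_", j, c("_tslv", "_r1", "_r2", "_r3", "_end_r1"))))
  }
  c(out, End_r1 = if (is.na(end_aoi)) 0 else end_aoi)
}

# AOI of the fixation with the latest onset among those overlapping window w
# (NA when w < 1, the window has no fixations, or the last one is whitespace).
last_fixation_aoi_in_window <- function(hits, w, tau_s) {
  if (w < 1) return(NA_integer_)
  To <- (w - 1) * tau_s * 1000
  Tf <- w * tau_s * 1000
  inw <- hits[hits$onset_ms < Tf & hits$offset_ms > To, , drop = FALSE]
  if (!nrow(inw)) return(NA_integer_)
  inw$aoi[which.max(inw$onset_ms)]
}

# id of the last component fixated in window w (skipping whitespace hits),
# or NA when none.
last_component_in_window <- function(hits, w, tau_s) {
  if (w < 1) return(NA_character_)
  To <- (w - 1) * tau_s * 1000
  Tf <- w * tau_s * 1000
  inw <- hits[hits$onset_ms < Tf & hits$offset_ms > To &
                hits$component != "whitespace", , drop = FALSE]
  if (!nrow(inw)) return(NA_character_)
  inw$component[which.max(inw$onset_ms)]
}

#' Component visit-history features for one window
#'
#' Per component: `his` (ever fixated before the window), `end_r1` (one-hot
#' of the last component fixated in window t-1), `tslv` (s since last visit),
#' `atv` (mean fixation duration on the component so far, ms) and `atbv`
#' (mean gap between consecutive fixations on it, ms); plus the shared
#' `Comp_end` integer (index of the `end_r1` component, 0 when none).
#'
#' @inheritParams aoi_history_features
#' @param components Character vector of component ids (layout order).
#' @return Named numeric vector.
#' @export
component_history_features <- function(hits, components, t, tau_s) {
  To <- (t - 1) * tau_s * 1000
  end_comp <- last_component_in_window(hits, t - 1L, tau_s)
  out <- numeric(0)
  for (ci in seq_along(components)) {
    cid <- components[ci]
    past <- hits[hits$component == cid & hits$onset_ms < To, , drop = FALSE]
    if (nrow(past)) {
      his <- 1
      tslv <- (To - min(max(past$offset_ms), To)) / 1000
      atv <- mean(past$duration_ms)
      atbv <- if (nrow(past) >= 2) {
        o <- order(past$onset_ms)
        mean(past$onset_ms[o][-1] - past$offset_ms[o][-nrow(past)])
      } else 0
    } else {
      his <- 0; tslv <- 0; atv <- 0; atbv <- 0
    }
    out <- c(out, setNames(c(his, as.numeric(identical(end_comp, cid)),
                             tslv, atv, atbv),
                           paste0(cid, c("_his", "_end_r1", "_tslv", "_atv", "_atbv"))))
  }
  c(out, Comp_end = if (is.na(end_comp)) 0 else match(end_comp, components))
}

#' Population-level AOI heat
#'
#' Fraction of training-fold recordings whose visit-intention label at the
#' same window index `t` is active, per AOI; 0 when no training recording
#' reaches window `t`. Test-fold users never contribute.
#'
#' @param training_labels List of binary label matrices (training fold).
#' @param t Window index.
#' @param n_aoi Number of AOIs.
#' @return Named numeric vector `Heat_AOI_1..n` in `[0, 1]`.
#' @export
heat_aoi <- function(training_labels, t, n_aoi) {
  rows <- lapply(training_labels, function(Y) if (nrow(Y) >= t) Y[t, ] else NULL)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  v <- if (length(rows)) colMeans(do.call(rbind, rows)) else numeric(n_aoi)
  setNames(as.numeric(v), paste0("Heat_AOI_", seq_len(n_aoi)))
}

# Interior central-difference derivative series over one chain of samples.
# Returns positions' first derivative at samples 2..(n-1); exact for linear
# motion, and its second-derivative companion is exact for quadratics.
chain_derivative <- function(t_s, v) {
  n <- length(v)
  if (n < 3) return(list(t = numeric(0), d = numeric(0)))
  i <- 2:(n - 1)
  list(t = t_s[i], d = (v[i + 1] - v[i - 1]) / (t_s[i + 1] - t_s[i - 1]))
}

chain_second_derivative <- function(t_s, v) {
  n <- length(v)
  if (n < 3) return(list(t = numeric(0), d = numeric(0)))
  i <- 2:(n - 1)
  h1 <- t_s[i] - t_s[i - 1]
  h2 <- t_s[i + 1] - t_s[i]
  list(t = t_s[i],
       d = 2 * ((v[i + 1] - v[i]) / h2 - (v[i] - v[i - 1]) / h1) / (h1 + h2))
}

#' Gaze kinematics of the previous window
#'
#' Position, velocity and acceleration summaries of the valid gaze samples in
#' window `t-1`: last position (`coordX`/`coordY`), mean and sd of position,
#' and for each axis the central-difference velocity (px/s) and acceleration
#' (px/s^2) series — their last value and their mean and sd over the window.
#' Invalid samples and temporal gaps larger than `gap_break_ms` break the
#' difference chains; windows with too few samples yield zeros.
#'
#' @param samples Sample data frame of the recording.
#' @param t Window index (>= 2).
#' @param tau_s Window length in seconds.
#' @param gap_break_ms Chain-break threshold in ms.
#' @return Named vector of 18 values.
#' @export
kinematics_features <- function(samples, t, tau_s, gap_break_ms = 2.5 * 1000 / 120) {
  To_prev <- (t - 2) * tau_s * 1000
  Tf_prev <- (t - 1) * tau_s * 1000
  s <- samples[samples$valid & samples$t_ms >= To_prev & samples$t_ms < Tf_prev, ,
               drop = FALSE]
  axis_feats <- function(x, t_s) {
    f <- c(coord = 0, Mean = 0, Std = 0, Vel = 0, MeanVel = 0, StdVel = 0,
           Acl = 0, MeanAcl = 0, StdAcl = 0)
    if (!length(x)) return(f)
    f["coord"] <- x[length(x)]
    f["Mean"] <- mean(x)
    f["Std"] <- if (length(x) > 1) stats::sd(x) else 0
    chains <- split(seq_along(x), cumsum(c(TRUE, diff(t_s) * 1000 > gap_break_ms)))
    vel_t <- vel <- acl_t <- acl <- numeric(0)
    for (ch in chains) {
      d1 <- chain_derivative(t_s[ch], x[ch])
      d2 <- chain_second_derivative(t_s[ch], x[ch])
      vel_t <- c(vel_t, d1$t); vel <- c(vel, d1$d)
      acl_t <- c(acl_t, d2$t); acl <- c(acl, d2$d)
    }
    if (length(vel)) {
      f["Vel"] <- vel[which.max(vel_t)]
      f["MeanVel"] <- mean(vel)
      f["StdVel"] <- if (length(vel) > 1) stats::sd(vel) else 0
    }
    if (length(acl)) {
      f["Acl"] <- acl[which.max(acl_t)]
      f["MeanAcl"] <- mean(acl)
      f["StdAcl"] <- if (length(acl) > 1) stats::sd(acl) else 0
    }
    f
  }
  t_s <- s$t_ms / 1000
  fx <- axis_feats(s$x_px, t_s)
  fy <- axis_feats(s$y_px, t_s)
  c(setNames(fx, paste0(names(fx), "X")), setNames(fy, paste0(names(fy), "Y")))
}

#' Oculomotor history statistics
#'
#' Counts and duration/amplitude summaries of all fixations and saccades of
#' the user before the start of window `t`; zeros when the history is empty.
#'
#' @param fixations,saccades Tables of the recording.
#' @param t Window index.
#' @param tau_s Window length in seconds.
#' @return Named vector of 8 values (`NFix`, `TPromFix`, `TMaxFix`,
#'   `TMinFix` in ms; `NSac`, `APromSac`, `AMaxSac`, `AMinSac` in px).
#' @export
oculomotor_features <- function(fixations, saccades, t, tau_s) {
  To <- (t - 1) * tau_s * 1000
  if (is.null(fixations$duration_ms)) {
    fixations$duration_ms <- fixations$offset_ms - fixations$onset_ms
  }
  fx <- fixations[fixations$onset_ms < To, , drop = FALSE]
  # only saccades completed before the window start are history
  sc <- saccades[saccades$onset_ms + saccades$duration_ms < To, , drop = FALSE]
  c(NFix = nrow(fx),
    TPromFix = if (nrow(fx)) mean(fx$duration_ms) else 0,
    TMaxFix = if (nrow(fx)) max(fx$duration_ms) else 0,
    TMinFix = if (nrow(fx)) min(fx$duration_ms) else 0,
    NSac = nrow(sc),
    APromSac = if (nrow(sc)) mean(sc$amplitude_px) else 0,
    AMaxSac = if (nrow(sc)) max(sc$amplitude_px) else 0,
    AMinSac = if (nrow(sc)) min(sc$amplitude_px) else 0)
}

#' Extract all fold-independent features of a recording
#'
#' One row per instance (windows `t = 2..floor(T/tau)`); the `Heat_AOI`
#' columns are left at `NA` and filled per training fold by
#' [build_design_matrix()].
#'
#' @param recording A `gaze_recording` with filtered fixations.
#' @param layout An `aoi_layout`.
#' @param tau_s Window length in seconds.
#' @param labels Optional precomputed [label_windows()] matrix.
#' @param hits Optional precomputed [fixation_hits()] table.
#' @return List with `keys` (data frame `user`, `session`, `window`),
#'   `X` (numeric matrix, columns = [feature_registry()]), `Y` (label matrix
#'   rows aligned to `X`), `labels` (full per-window label matrix).
#' @export
extract_features <- function(recording, layout, tau_s,
                             labels = NULL, hits = NULL) {
  if (is.null(hits)) hits <- fixation_hits(recording, layout)
  if (is.null(labels)) labels <- label_windows(recording, layout, tau_s, hits = hits)
  reg <- feature_registry(layout)
  W <- nrow(labels)
  ts <- if (W >= 2) 2:W else integer(0)
  X <- matrix(NA_real_, nrow = length(ts), ncol = length(reg),
              dimnames = list(NULL, reg))
  for (i in seq_along(ts)) {
    t <- ts[i]
    row <- c(aoi_history_features(labels, hits, t, tau_s),
             component_history_features(hits, layout$components$id, t, tau_s),
             kinematics_features(recording$samples, t, tau_s),
             oculomotor_features(recording$fixations, recording$saccades, t, tau_s))
    X[i, names(row)] <- row
  }
  list(
    keys = data.frame(user = rep(recording$user_id, length(ts)),
                      session = rep(recording$session_id, length(ts)),
                      window = ts, stringsAsFactors = FALSE),
    X = X,
    Y = labels[ts, , drop = FALSE],
    labels = labels)
}

#' Build train/test design matrices for one fold
#'
#' Extracts (or reuses) per-recording features, fills the `Heat_AOI` columns
#' from the training-fold recordings only, and splits instances by the fold
#' assignment. The feature registry is identical between train and test.
#'
#' @param recordings List of `gaze_recording`s with filtered fixations.
#' @param layout An `aoi_layout`.
#' @param tau_s Window length in seconds.
#' @param fold_assignment A [assign_folds()] result (names = user ids).
#' @param k Test-fold index.
#' @param extracted Optional list of [extract_features()] results aligned to
#'   `recordings` (reused across folds).
#' @return List with `train` and `test`, each `list(X, Y, keys)`, and
#'   `registry`.
#' @export
build_design_matrix <- function(recordings, layout, tau_s, fold_assignment, k,
                                extracted = NULL) {
  if (is.null(extracted)) {
    extracted <- lapply(recordings, extract_features, layout = layout, tau_s = tau_s)
  }
  users <- vapply(recordings, `[[`, character(1), "user_id")
  stopifnot(all(users %in% names(fold_assignment$fold)))
  test_users <- names(fold_assignment$fold)[fold_assignment$fold == k]
  is_test <- users %in% test_users
  train_labels <- lapply(extracted[!is_test], `[[`, "labels")
  n <- layout$n_aoi
  heat_cols <- paste0("Heat_AOI_", seq_len(n))
  max_t <- max(c(2L, vapply(extracted, function(e) nrow(e$labels), integer(1))))
  heat_by_t <- t(vapply(seq_len(max_t), function(t) heat_aoi(train_labels, t, n),
                        numeric(n)))
  fill <- function(sel) {
    parts <- extracted[sel]
    parts <- parts[vapply(parts, function(e) nrow(e$X) > 0, logical(1))]
    if (!length(parts)) {
      reg <- feature_registry(layout)
      return(list(X = matrix(numeric(0), 0, length(reg), dimnames = list(NULL, reg)),
                  Y = matrix(integer(0), 0, n),
                  keys = data.frame(user = character(0), session = character(0),
                                    window = integer(0))))
    }
    X <- do.call(rbind, lapply(parts, `[[`, "X"))
    Y <- do.call(rbind, lapply(parts, `[[`, "Y"))
    keys <- do.call(rbind, lapply(parts, `[[`, "keys"))
    X[, heat_cols] <- heat_by_t[keys$window, , drop = FALSE]
    rownames(X) <- rownames(Y) <- NULL
    list(X = X, Y = Y, keys = keys)
  }
  list(train = fill(!is_test), test = fill(is_test),
       registry = feature_registry(layout))
}
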
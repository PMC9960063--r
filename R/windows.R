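# Window segmentation, visit-intention labels and majority-class baselines.
#
# A recording of total length T is tiled by floor(T / tau) consecutive
# tau-second windows starting at 0; any partial remainder is discarded. The
# visit-intention label of window t is the binary vector over AOIs saying
# whether at least one (filtered) fixation overlapping the window hit-tests
# to that AOI at its onset time.

#' Segment a recording into tau-second windows
#'
#' @param recording A `gaze_recording`, or a duration in ms.
#' @param tau_s Window length in seconds (> 0).
#' @return Data frame with `window` (1..floor(T/tau)), `To_ms`, `Tf_ms`;
#'   zero rows when the recording is shorter than one window.
#' @export
segment_windows <- function(recording, tau_s) {
  stopifnot(tau_s > 0)
  T_ms <- if (inherits(recording, "gaze_recording")) recording$duration_ms
          else as.numeric(recording)
  w <- floor(T_ms / (tau_s * 1000))
  if (w < 1) {
    return(data.frame(window = integer(0), To_ms = numeric(0), Tf_ms = numeric(0)))
  }
  t <- seq_len(w)
  data.frame(window = t, To_ms = (t - 1) * tau_s * 1000, Tf_ms = t * tau_s * 1000)
}

#' Hit-test a recording's fixations
#'
#' Resolves every fixation's centroid to a component and AOI at its onset
#' time (the pop-up state may change mid-fixation; attribution is fixed at
#' onset).
#'
#' @param recording A `gaze_recording` with filtered fixations.
#' @param layout An `aoi_layout`.
#' @param state Optional `layout_state`; defaults to the one implied by the
#'   recording's events.
#' @return The fixation table with `component` and `aoi` columns appended.
#' @export
fixation_hits <- function(recording, layout, state = NULL) {
  if (is.null(state)) state <- layout_state(recording$events, recording$duration_ms)
  fx <- recording$fixations
  if (!nrow(fx)) {
    fx$component <- character(0)
    fx$aoi <- integer(0)
    return(fx)
  }
  h <- hit_test(cbind(fx$cx_px, fx$cy_px), fx$onset_ms, layout, state)
  fx$component <- h$component
  fx$aoi <- h$aoi
  fx
}

#' Visit-intention labels per window
#'
#' `Iv(A_j, v(t)) = 1` iff some fixation whose `[onset, offset)` overlaps
#' `[To(t), Tf(t))` hit-tests to AOI j at its onset; a fixation spanning a
#' window boundary labels both windows.
#'
#' @param recording A `gaze_recording` whose fixations are already filtered
#'   (>= 100 ms).
#' @param layout An `aoi_layout`.
#' @param tau_s Window length in seconds.
#' @param hits Optional precomputed [fixation_hits()] table.
#' @return Binary matrix, `floor(T/tau)` rows by `n_aoi` columns, with
#'   `dimnames` `list(window, AOI_j)`.
#' @export
label_windows <- function(recording, layout, tau_s, hits = NULL) {
  wins <- segment_windows(recording, tau_s)
  n <- layout$n_aoi
  Y <- matrix(0L, nrow = nrow(wins), ncol = n,
              dimnames = list(wins$window, paste0("AOI_", seq_len(n))))
  if (!nrow(wins)) return(Y)
  if (is.null(hits)) hits <- fixation_hits(recording, layout)
  hits <- hits[!is.na(hits$aoi), , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    overlap <- hits$onset_ms[i] < wins$Tf_ms & hits$offset_ms[i] > wins$To_ms
    Y[overlap, hits$aoi[i]] <- 1L
  }
  Y
}

#' Majority-class baselines
#'
#' Per AOI, the modal value of the label column and its frequency; for the
#' whole vector, the frequency of the modal visit-intention vector. A tie at
#' 0.5 reports class 1.
#'
#' @param labels A binary label matrix, or a list of them (stacked).
#' @return List with `per_aoi` (data frame: `aoi`, `class`, `ratio`) and
#'   `vector_mc` (list: `vector`, `ratio`).
#' @export
majority_class_ratio <- function(labels) {
  if (is.list(labels) && !is.data.frame(labels)) labels <- do.call(rbind, labels)
  labels <- as.matrix(labels)
  if (!nrow(labels)) stop("majority_class_ratio needs at least one instance")
  p1 <- colMeans(labels)
  cls <- as.integer(p1 >= 0.5)               # tie at 0.5 -> class 1
  ratio <- ifelse(cls == 1L, p1, 1 - p1)
  keys <- apply(labels, 1, paste, collapse = "")
  tab <- sort(table(keys), decreasing = TRUE)
  list(
    per_aoi = data.frame(aoi = seq_len(ncol(labels)), class = cls,
                         ratio = as.numeric(ratio)),
    vector_mc = list(
      vector = as.integer(strsplit(names(tab)[1], "")[[1]]),
      ratio = as.numeric(tab[1]) / nrow(labels)))
}
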
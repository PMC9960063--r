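# Gaze signal containers and I/O.
#
# A recording bundles the raw 120 Hz gaze samples, the fixation list (either
# read from an external fixation log or detected with the I-DT fallback), the
# saccades derived from consecutive fixations, and the interaction events
# (scroll, pop-up open/close, click) that drive the dynamic layout.

#' Construct a gaze recording
#'
#' Bundles gaze samples, fixations, saccades and interaction events for one
#' user session. Samples must be strictly increasing in time; fixations must
#' be time-ordered and non-overlapping.
#'
#' @param user_id,session_id Identifiers (coerced to character).
#' @param samples Data frame with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @param fixations Data frame with columns `onset_ms`, `offset_ms`, `cx_px`,
#'   `cy_px`, or `NULL`.
#' @param events Data frame with columns `t_ms`, `kind`, `payload`, or `NULL`.
#'   `kind` is one of `"scroll"`, `"popup_open"`, `"popup_close"`, `"click"`.
#' @param duration_ms Total recording span; defaults to the last sample time.
#' @param fixation_source `"log"` when fixations come from an external
#'   detector's log, `"idt"` when produced by [detect_fixations_idt()].
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(user_id, session_id, samples,
                           fixations = NULL, events = NULL,
                           duration_ms = NULL, fixation_source = "log") {
  stopifnot(is.data.frame(samples))
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns ", paste(need, collapse = ", "))
  }
  samples <- samples[order(samples$t_ms), need, drop = FALSE]
  if (nrow(samples) > 1 && any(diff(samples$t_ms) <= 0)) {
    stop("sample timestamps must be strictly increasing")
  }
  bad <- samples$valid & (!is.finite(samples$x_px) | !is.finite(samples$y_px))
  if (any(bad)) stop("valid samples must have finite coordinates")
  if (is.null(fixations)) {
    fixations <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                            cx_px = numeric(0), cy_px = numeric(0))
  }
  fixations <- validate_fixations(fixations)
  if (is.null(events)) {
    events <- data.frame(t_ms = numeric(0), kind = character(0),
                         payload = character(0), stringsAsFactors = FALSE)
  }
  kinds <- c("scroll", "popup_open", "popup_close", "click")
  if (nrow(events) && !all(events$kind %in% kinds)) {
    stop("unknown event kind: ",
         paste(setdiff(unique(events$kind), kinds), collapse = ", "))
  }
  events <- events[order(events$t_ms), , drop = FALSE]
  if (is.null(duration_ms)) {
    duration_ms <- max(c(samples$t_ms, fixations$offset_ms, events$t_ms, 0))
  }
  if (nrow(samples) && duration_ms < max(samples$t_ms)) {
    stop("duration_ms is shorter than the last sample")
  }
  structure(list(
    user_id = as.character(user_id),
    session_id = as.character(session_id),
    samples = samples,
    fixations = fixations,
    saccades = derive_saccades(fixations),
    events = events,
    duration_ms = duration_ms,
    fixation_source = fixation_source
  ), class = "gaze_recording")
}

validate_fixations <- function(fixations) {
  need <- c("onset_ms", "offset_ms", "cx_px", "cy_px")
  if (!all(need %in% names(fixations))) {
    stop("fixations must have columns ", paste(need, collapse = ", "))
  }
  fixations <- fixations[order(fixations$onset_ms), need, drop = FALSE]
  rownames(fixations) <- NULL
  if (nrow(fixations)) {
    if (any(fixations$offset_ms <= fixations$onset_ms)) {
      stop("fixations must have positive duration")
    }
    if (nrow(fixations) > 1 &&
        any(fixations$onset_ms[-1] < fixations$offset_ms[-nrow(fixations)])) {
      stop("fixations must be non-overlapping and time-ordered")
    }
  }
  fixations$duration_ms <- fixations$offset_ms - fixations$onset_ms
  fixations
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> user %s session %s: %d samples, %d fixations (%s), %d events, %.1f s\n",
    x$user_id, x$session_id, nrow(x$samples), nrow(x$fixations),
    x$fixation_source, nrow(x$events), x$duration_ms / 1000))
  invisible(x)
}

#' Read a gaze log from CSV
#'
#' Reads the sample log (`t_ms,x_px,y_px,valid`) and, optionally, companion
#' fixation (`onset_ms,offset_ms,cx_px,cy_px`) and event (`t_ms,kind,payload`)
#' logs, returning a validated [gaze_recording()]. Rows flagged invalid are
#' retained but excluded from downstream fixation detection and kinematics.
#'
#' @param path Path to the sample CSV.
#' @param fixation_path,event_path Optional companion CSV paths.
#' @param user_id,session_id Identifiers stored on the recording.
#' @return A `gaze_recording`.
#' @export
read_gaze_log <- function(path, fixation_path = NULL, event_path = NULL,
                          user_id = "u", session_id = "s") {
  samples <- read_checked_csv(path, c(t_ms = "numeric", x_px = "numeric",
                                      y_px = "numeric", valid = "logical"))
  fixations <- NULL
  if (!is.null(fixation_path)) {
    fixations <- read_checked_csv(fixation_path,
      c(onset_ms = "numeric", offset_ms = "numeric",
        cx_px = "numeric", cy_px = "numeric"))
  }
  events <- NULL
  if (!is.null(event_path)) {
    events <- read_checked_csv(event_path,
      c(t_ms = "numeric", kind = "character", payload = "character"))
  }
  gaze_recording(user_id, session_id, samples, fixations, events,
                 fixation_source = if (is.null(fixation_path)) "none" else "log")
}

# Reads a CSV and type-checks each column, reporting the first offending
# data line (1-based, excluding the header) on failure.
read_checked_csv <- function(path, coltypes) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(coltypes), names(raw))
  if (length(missing)) {
    stop("file ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- raw[names(coltypes)]
  for (col in names(coltypes)) {
    v <- out[[col]]
    if (coltypes[[col]] == "numeric") {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("parse error in %s: line %d, column '%s' is not numeric (%s)",
                     path, bad[1], col, v[bad[1]]))
      }
      out[[col]] <- parsed
    } else if (coltypes[[col]] == "logical") {
      parsed <- v %in% c("TRUE", "true", "1", "T")
      ok <- v %in% c("TRUE", "true", "1", "T", "FALSE", "false", "0", "F")
      if (!all(ok)) {
        stop(sprintf("parse error in %s: line %d, column '%s' is not logical (%s)",
                     path, which(!ok)[1], col, v[which(!ok)[1]]))
      }
      out[[col]] <- parsed
    }
  }
  out
}

#' Write a recording's logs to CSV
#'
#' Writes the sample, fixation and event logs of a recording to
#' `<prefix>_gaze.csv`, `<prefix>_fix.csv` and `<prefix>_events.csv`, the
#' formats accepted by [read_gaze_log()].
#'
#' @param recording A `gaze_recording`.
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three paths written.
#' @export
write_gaze_log <- function(recording, prefix) {
  stopifnot(inherits(recording, "gaze_recording"))
  paths <- paste0(prefix, c("_gaze.csv", "_fix.csv", "_events.csv"))
  utils::write.csv(recording$samples, paths[1], row.names = FALSE, quote = FALSE)
  fix <- recording$fixations[c("onset_ms", "offset_ms", "cx_px", "cy_px")]
  utils::write.csv(fix, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(recording$events, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Fallback detector for recordings whose fixation log is unavailable. Scans
#' the valid samples for maximal windows whose dispersion
#' `(max(x) - min(x)) + (max(y) - min(y))` stays within `dispersion_px` and
#' whose span reaches `min_duration_ms`; the fixation centroid is the mean of
#' the member samples. Invalid samples and temporal gaps larger than
#' `gap_break_ms` break candidate windows.
#'
#' @param recording A `gaze_recording` (or a sample data frame).
#' @param dispersion_px Maximum summed x+y dispersion, in pixels.
#' @param min_duration_ms Minimum fixation span, in milliseconds.
#' @param gap_break_ms Temporal gap (ms) above which the sample chain is cut;
#'   defaults to 2.5 nominal 120 Hz intervals.
#' @return A fixation data frame (`onset_ms`, `offset_ms`, `cx_px`, `cy_px`,
#'   `duration_ms`); empty when no window qualifies.
#' @export
detect_fixations_idt <- function(recording, dispersion_px = 60,
                                 min_duration_ms = 100,
                                 gap_break_ms = 2.5 * 1000 / 120) {
  stopifnot(dispersion_px > 0, min_duration_ms > 0)
  samples <- if (inherits(recording, "gaze_recording")) recording$samples else recording
  s <- samples[samples$valid, , drop = FALSE]
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      cx_px = numeric(0), cy_px = numeric(0),
                      duration_ms = numeric(0))
  if (nrow(s) < 2) return(empty)
  # contiguous chains of valid samples
  cut <- c(TRUE, diff(s$t_ms) > gap_break_ms)
  chain <- cumsum(cut)
  out <- list()
  for (ch in split(seq_len(nrow(s)), chain)) {
    t <- s$t_ms[ch]; x <- s$x_px[ch]; y <- s$y_px[ch]
    n <- length(t)
    i <- 1L
    while (i <= n) {
      j <- i
      xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
      while (j < n) {
        nx <- x[j + 1L]; ny <- y[j + 1L]
        d <- (max(xmax, nx) - min(xmin, nx)) + (max(ymax, ny) - min(ymin, ny))
        if (d > dispersion_px) break
        j <- j + 1L
        xmin <- min(xmin, nx); xmax <- max(xmax, nx)
        ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      }
      if (t[j] - t[i] >= min_duration_ms) {
        idx <- i:j
        out[[length(out) + 1L]] <- data.frame(
          onset_ms = t[i], offset_ms = t[j],
          cx_px = mean(x[idx]), cy_px = mean(y[idx]))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) return(empty)
  validate_fixations(do.call(rbind, out))
}

#' Filter out short fixations
#'
#' Drops fixations shorter than `min_duration_ms`; the comparison is strict,
#' so a fixation of exactly the threshold duration is kept.
#'
#' @param fixations Fixation data frame.
#' @param min_duration_ms Threshold in milliseconds (default 100).
#' @return The surviving fixations, order preserved.
#' @export
filter_short_fixations <- function(fixations, min_duration_ms = 100) {
  fixations <- validate_fixations(fixations)
  out <- fixations[fixations$duration_ms >= min_duration_ms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive saccades from consecutive fixations
#'
#' One saccade per consecutive fixation pair: amplitude is the Euclidean
#' distance between centroids, duration the gap between the first fixation's
#' offset and the next one's onset.
#'
#' @param fixations Time-ordered fixation data frame.
#' @return Data frame with `from_fix`, `to_fix`, `onset_ms`, `duration_ms`,
#'   `amplitude_px`; empty when fewer than two fixations.
#' @export
derive_saccades <- function(fixations) {
  empty <- data.frame(from_fix = integer(0), to_fix = integer(0),
                      onset_ms = numeric(0), duration_ms = numeric(0),
                      amplitude_px = numeric(0))
  n <- nrow(fixations)
  if (is.null(n) || n < 2) return(empty)
  i <- seq_len(n - 1L)
  data.frame(
    from_fix = i,
    to_fix = i + 1L,
    onset_ms = fixations$offset_ms[i],
    duration_ms = fixations$onset_ms[i + 1L] - fixations$offset_ms[i],
    amplitude_px = sqrt((fixations$cx_px[i + 1L] - fixations$cx_px[i])^2 +
                        (fixations$cy_px[i + 1L] - fixations$cy_px[i])^2))
}

#' Replace a recording's fixations
#'
#' Installs a new fixation table (e.g. the output of [detect_fixations_idt()]
#' or [filter_short_fixations()]) and rederives the saccades.
#'
#' @param recording A `gaze_recording`.
#' @param fixations Fixation data frame.
#' @param source Provenance tag stored on the recording.
#' @return The updated recording.
#' @export
set_fixations <- function(recording, fixations, source = "idt") {
  stopifnot(inherits(recording, "gaze_recording"))
  recording$fixations <- validate_fixations(fixations)
  recording$saccades <- derive_saccades(recording$fixations)
  recording$fixation_source <- source
  recording
}
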
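# Synthetic browsing cohorts.
#
# The generator emulates the statistical structure the prediction method
# assumes: users perform a semi-Markov walk over 6 AOIs plus whitespace
# (explicit fixation dwells of 100-3273 ms, saccade gaps of 30-80 ms,
# 120 Hz gaze samples), on a one-page layout that scrolls and shows an
# occluding registration pop-up (AOI 6). Population-level structure comes
# from shared, slowly drifting AOI preferences (early windows favour the
# top of the page, late windows the bottom), which per-user transition
# matrices perturb; this time-locked drift is what makes the population
# Heat_AOI feature informative. Whitespace is an explicit state so that
# windows with no active AOI occur.

#' Default one-page layout for synthetic cohorts
#'
#' A 1280x1024 viewport over a 1280x2000 page: a sticky logo + menu bar
#' (AOI 1), two news groups (AOIs 2 and 3), two advertising banner groups
#' (AOIs 4 and 5) and a registration pop-up (AOI 6) that occludes the page
#' while open. Title, page-number button and subscription button belong to
#' no AOI (whitespace).
#'
#' @return An `aoi_layout`.
#' @export
default_layout <- function() {
  comps <- data.frame(
    id = c("Logo", "Bar_Menu", "Sub_Butt", "Title",
           "New_1", "New_2", "New_3", "New_4", "New_5", "New_6", "New_7",
           "Banner_1", "Banner_2", "Banner_3", "Banner_4",
           "Num_Pag", "Reg_Pop"),
    x0 = c(20, 200, 1000, 20, 20, 20, 20, 20, 20, 20, 20,
           660, 660, 660, 660, 20, 340),
    y0 = c(10, 10, 10, 90, 170, 390, 610, 860, 1080, 1300, 1520,
           170, 490, 860, 1180, 1760, 250),
    x1 = c(180, 980, 1260, 900, 620, 620, 620, 620, 620, 620, 620,
           960, 960, 960, 960, 300, 940),
    y1 = c(70, 70, 70, 150, 370, 590, 810, 1060, 1280, 1500, 1720,
           470, 790, 1160, 1480, 1820, 750),
    sticky = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 12), TRUE))
  aoi_layout(
    screen = c(1280, 1024),
    components = comps,
    aois = list(
      list(index = 1, components = c("Logo", "Bar_Menu"),
           dynamic = TRUE, occludes_below = FALSE),
      list(index = 2, components = c("New_1", "New_2", "New_3"),
           dynamic = FALSE, occludes_below = FALSE),
      list(index = 3, components = c("New_4", "New_5", "New_6", "New_7"),
           dynamic = FALSE, occludes_below = FALSE),
      list(index = 4, components = c("Banner_1", "Banner_2"),
           dynamic = FALSE, occludes_below = FALSE),
      list(index = 5, components = c("Banner_3", "Banner_4"),
           dynamic = FALSE, occludes_below = FALSE),
      list(index = 6, components = "Reg_Pop",
           dynamic = TRUE, occludes_below = TRUE)))
}

#' Construct a synthetic user profile
#'
#' @param pref Length-7 preference vector over states (AOIs 1..6 then
#'   whitespace); normalized internally.
#' @param stick Self-transition probability (run persistence).
#' @param trans Optional explicit 7x7 transition matrix (rows sum to 1);
#'   overrides `pref`/`stick` and the population drift.
#' @param dwell_meanlog,dwell_sdlog Log-normal fixation-dwell parameters
#'   (ms); dwells are truncated to `[100, 3273]` ms.
#' @param noise_px Gaussian gaze-noise sd in pixels.
#' @param invalid_rate Fraction of samples flagged invalid (track loss).
#' @return A `user_profile` list.
#' @export
user_profile <- function(pref = c(0.12, 0.22, 0.20, 0.12, 0.10, 0.03, 0.21),
                         stick = 0.72, trans = NULL,
                         dwell_meanlog = log(220), dwell_sdlog = 0.45,
                         noise_px = 10, invalid_rate = 0.02) {
  stopifnot(length(pref) == 7, all(pref >= 0), sum(pref) > 0)
  if (!is.null(trans)) {
    trans <- as.matrix(trans)
    stopifnot(nrow(trans) == 7, ncol(trans) == 7, all(trans >= 0))
    if (any(abs(rowSums(trans) - 1) > 1e-8)) {
      stop("transition matrix rows must sum to 1")
    }
  }
  structure(list(pref = pref / sum(pref), stick = stick, trans = trans,
                 dwell_meanlog = dwell_meanlog, dwell_sdlog = dwell_sdlog,
                 noise_px = noise_px, invalid_rate = invalid_rate),
            class = "user_profile")
}

# Shared population drift: early browsing favours the top of the page
# (menu, first news group), late browsing the bottom (second banner group).
phase_preference <- function(frac) {
  p1 <- c(0.30, 0.30, 0.10, 0.08, 0.04, 0.02, 0.16)
  p2 <- c(0.08, 0.18, 0.30, 0.18, 0.08, 0.03, 0.15)
  p3 <- c(0.06, 0.10, 0.16, 0.18, 0.30, 0.04, 0.16)
  if (frac < 1 / 3) p1 else if (frac < 2 / 3) p2 else p3
}

#' Effective transition matrix of a profile at a point in the recording
#'
#' Row `i` = `stick * e_i + (1 - stick) * normalize(pref * phase)`, unless
#' the profile carries an explicit matrix.
#'
#' @param profile A `user_profile`.
#' @param frac Fraction of the recording elapsed (in `[0, 1]`).
#' @return 7x7 stochastic matrix.
#' @export
transition_matrix <- function(profile, frac = 0) {
  if (!is.null(profile$trans)) return(profile$trans)
  mix <- profile$pref * phase_preference(frac)
  mix <- mix / sum(mix)
  M <- matrix(mix, 7, 7, byrow = TRUE) * (1 - profile$stick)
  diag(M) <- diag(M) + profile$stick
  M / rowSums(M)
}

#' Sample a synthetic population
#'
#' Per-user transition preferences are drawn around the shared population
#' tendencies (log-normal multiplicative perturbation), so cross-user
#' window-wise AOI frequencies carry signal; perturbation scale 0 makes all
#' users identical.
#'
#' @param n_users Number of users (default 51, the study scale).
#' @param sessions Recordings per user (default 3).
#' @param duration_s Recording length in seconds: a number, a function of no
#'   arguments, or `NULL` for the default log-normal (mean ~79 s, sd ~52 s,
#'   truncated to 16.5-399 s).
#' @param perturb Per-user log-normal perturbation scale (default 0.4).
#' @param noise_px,invalid_rate Passed to every [user_profile()].
#' @param rate_hz Sampling rate (default 120).
#' @param seed Integer seed.
#' @return A `population_model`: list with `layout`, `profiles`,
#'   `durations` (users x sessions), and the settings.
#' @export
sample_population <- function(n_users = 51, sessions = 3, duration_s = NULL,
                              perturb = 0.4, noise_px = 10,
                              invalid_rate = 0.02, rate_hz = 120, seed = 1) {
  stopifnot(n_users >= 2, sessions >= 1, rate_hz > 0)
  set.seed(seed)
  base <- c(0.12, 0.22, 0.20, 0.12, 0.10, 0.03, 0.21)
  profiles <- lapply(seq_len(n_users), function(u) {
    pref <- base * exp(stats::rnorm(7, 0, perturb))
    stick <- stats::plogis(stats::qlogis(0.72) + stats::rnorm(1, 0, 0.3))
    user_profile(pref = pref, stick = stick,
                 dwell_meanlog = log(220) + stats::rnorm(1, 0, 0.1),
                 noise_px = noise_px, invalid_rate = invalid_rate)
  })
  dur <- function() {
    if (is.function(duration_s)) return(duration_s())
    if (!is.null(duration_s)) return(duration_s)
    repeat {
      d <- stats::rlnorm(1, meanlog = 4.187, sdlog = 0.6)
      if (d >= 16.5 && d <= 399) return(d)
    }
  }
  durations <- matrix(vapply(seq_len(n_users * sessions), function(i) dur(),
                             numeric(1)), n_users, sessions)
  structure(list(layout = default_layout(), profiles = profiles,
                 durations = durations, n_users = n_users,
                 sessions = sessions, rate_hz = rate_hz, seed = seed),
            class = "population_model")
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

# pick a fixation target for a state; returns list(x, y, dy, scrolled)
# with x, y in screen coordinates and dy the (possibly updated) scroll
# offset ensuring the target is visible below the sticky bar
pick_target <- function(state, layout, dy) {
  comps <- layout$components
  screen_h <- layout$screen[2]
  page_h <- max(comps$y1[!comps$sticky])
  ids <- if (state <= 6) layout$aois[[state]]$components
         else c("Title", "Num_Pag")
  cid <- if (length(ids) > 1) sample(ids, 1) else ids
  cp <- comps[comps$id == cid, ]
  if (cp$sticky) {
    return(list(x = stats::runif(1, cp$x0 + 1, cp$x1 - 1),
                y = stats::runif(1, cp$y0 + 1, cp$y1 - 1),
                dy = dy, scrolled = FALSE))
  }
  scrolled <- FALSE
  bar_h <- 80  # keep page targets clear of the sticky bar
  if (cp$y0 < dy + bar_h || cp$y1 > dy + screen_h) {
    dy <- max(0, min((cp$y0 + cp$y1) / 2 - screen_h / 2, page_h - screen_h))
    dy <- max(dy, cp$y1 - screen_h)       # bottom edge visible
    dy <- min(dy, cp$y0 - bar_h)          # top edge below the bar
    dy <- max(0, round(dy))
    scrolled <- TRUE
  }
  list(x = stats::runif(1, cp$x0 + 1, cp$x1 - 1),
       y = stats::runif(1, cp$y0 + 1, cp$y1 - 1) - dy,
       dy = dy, scrolled = scrolled)
}

#' Simulate one browsing recording
#'
#' Semi-Markov walk over AOIs and whitespace: each state visit is a fixation
#' at a uniform point inside a member component (log-normal dwell truncated
#' to 100-3273 ms), separated by 30-80 ms saccade gaps. Scroll events keep
#' page-fixed targets visible; entering state 6 opens the registration
#' pop-up (occluding the page) and leaving it closes it. Gaze samples at
#' `rate_hz` follow the fixation centroids (linear sweeps during saccades)
#' with Gaussian jitter.
#'
#' @param profile A `user_profile`.
#' @param layout An `aoi_layout`.
#' @param duration_s Recording length in seconds.
#' @param rate_hz Sampling rate (default 120).
#' @param seed Integer seed.
#' @param user_id,session_id Identifiers for the recording.
#' @return A `gaze_recording` with ground truth attached as `$truth`
#'   (per-fixation generating state; AOI index or 7 for whitespace).
#' @export
simulate_recording <- function(profile, layout, duration_s, rate_hz = 120,
                               seed = 1, user_id = "u1", session_id = "s1") {
  set.seed(seed)
  dur_ms <- duration_s * 1000
  M0 <- transition_matrix(profile, 0)
  state <- sample.int(7, 1, prob = M0[7, ])
  t <- stats::runif(1, 30, 80)
  dy <- 0
  fx <- list(); ev <- list(); truth <- integer(0)
  popup_open <- FALSE
  repeat {
    dwell <- min(max(stats::rlnorm(1, profile$dwell_meanlog, profile$dwell_sdlog),
                     100), 3273)
    if (t + dwell > dur_ms) break
    tgt <- pick_target(state, layout, dy)
    if (tgt$scrolled) {
      ev[[length(ev) + 1L]] <- data.frame(t_ms = t - 5, kind = "scroll",
                                          payload = as.character(tgt$dy))
      dy <- tgt$dy
    }
    if (state == 6 && !popup_open) {
      ev[[length(ev) + 1L]] <- data.frame(t_ms = t - 2, kind = "popup_open",
                                          payload = "")
      popup_open <- TRUE
    }
    fx[[length(fx) + 1L]] <- data.frame(onset_ms = t, offset_ms = t + dwell,
                                        cx_px = tgt$x, cy_px = tgt$y)
    truth <- c(truth, state)
    t_next <- t + dwell + stats::runif(1, 30, 80)
    nxt <- sample.int(7, 1, prob = transition_matrix(profile, t / dur_ms)[state, ])
    if (popup_open && nxt != 6) {
      ev[[length(ev) + 1L]] <- data.frame(t_ms = t + dwell + 1,
                                          kind = "popup_close", payload = "")
      popup_open <- FALSE
    }
    state <- nxt
    t <- t_next
  }
  fixations <- if (length(fx)) do.call(rbind, fx) else NULL
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  # gaze samples: piecewise path through the fixation centroids
  ts <- seq(0, dur_ms, by = 1000 / rate_hz)
  n <- length(ts)
  x <- numeric(n); y <- numeric(n)
  if (!is.null(fixations) && nrow(fixations)) {
    onset <- fixations$onset_ms; offset <- fixations$offset_ms
    cx <- fixations$cx_px; cy <- fixations$cy_px
    k <- findInterval(ts, onset)
    for (i in seq_len(n)) {
      j <- k[i]
      if (j == 0) { x[i] <- cx[1]; y[i] <- cy[1] }
      else if (ts[i] <= offset[j] || j == length(onset)) {
        x[i] <- cx[j]; y[i] <- cy[j]
      } else {   # saccade sweep to the next centroid
        a <- (ts[i] - offset[j]) / (onset[j + 1] - offset[j])
        x[i] <- cx[j] + a * (cx[j + 1] - cx[j])
        y[i] <- cy[j] + a * (cy[j + 1] - cy[j])
      }
    }
  }
  if (profile$noise_px > 0) {
    x <- x + stats::rnorm(n, 0, profile$noise_px)
    y <- y + stats::rnorm(n, 0, profile$noise_px)
  }
  valid <- stats::runif(n) >= profile$invalid_rate
  samples <- data.frame(t_ms = ts, x_px = x, y_px = y, valid = valid)
  rec <- gaze_recording(user_id, session_id, samples, fixations, events,
                        duration_ms = dur_ms, fixation_source = "synthetic")
  rec$truth <- truth
  rec
}

#' Simulate a full cohort in memory
#'
#' @param population A [sample_population()] result.
#' @param seed Integer seed (recording seeds are derived from it).
#' @return List of `gaze_recording`s (users x sessions, user-major order).
#' @export
simulate_cohort <- function(population, seed = 1) {
  recs <- list()
  i <- 0L
  for (u in seq_len(population$n_users)) {
    for (s in seq_len(population$sessions)) {
      i <- i + 1L
      recs[[i]] <- simulate_recording(
        population$profiles[[u]], population$layout,
        population$durations[u, s], population$rate_hz,
        seed = derive_seed(seed, i),
        user_id = sprintf("user%02d", u), session_id = sprintf("s%d", s))
    }
  }
  recs
}

#' Write a cohort to disk
#'
#' Writes per-recording gaze/fixation/event CSVs, the layout JSON and a
#' manifest with the seeds and ground-truth profile parameters; byte-identical
#' across runs with the same seed.
#'
#' @param population A [sample_population()] result.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of recordings written.
#' @export
generate_cohort <- function(population, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- simulate_cohort(population, seed)
  for (r in recs) {
    write_gaze_log(r, file.path(out_dir, paste0(r$user_id, "_", r$session_id)))
  }
  write_layout(population$layout, file.path(out_dir, "layout.json"))
  manifest <- list(
    seed = seed, n_users = population$n_users, sessions = population$sessions,
    rate_hz = population$rate_hz,
    durations = population$durations,
    profiles = lapply(population$profiles, function(p)
      list(pref = p$pref, stick = p$stick, dwell_meanlog = p$dwell_meanlog,
           dwell_sdlog = p$dwell_sdlog, noise_px = p$noise_px,
           invalid_rate = p$invalid_rate)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(recs)
}
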
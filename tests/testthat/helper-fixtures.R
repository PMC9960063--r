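# Shared fixture builders (all data generated in code).

# samples at a constant point, 120 Hz
constant_samples <- function(t0, t1, x, y, rate = 120) {
  ts <- seq(t0, t1, by = 1000 / rate)
  data.frame(t_ms = ts, x_px = x, y_px = y, valid = TRUE)
}

make_fixations <- function(onset, offset, cx, cy) {
  data.frame(onset_ms = onset, offset_ms = offset, cx_px = cx, cy_px = cy)
}

# minimal recording wrapper for feature tests
make_recording <- function(samples = NULL, fixations = NULL, events = NULL,
                           duration_ms = NULL, user = "u1", session = "s1") {
  if (is.null(samples)) {
    samples <- data.frame(t_ms = c(0, 10), x_px = 0, y_px = 0, valid = TRUE)
  }
  gaze_recording(user, session, samples, fixations, events,
                 duration_ms = duration_ms)
}

# a small cached cohort shared by the heavier tests
small_cohort <- local({
  cache <- NULL
  function(n_users = 10, sessions = 2, duration_s = 60, seed = 11) {
    key <- paste(n_users, sessions, duration_s, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    pop <- sample_population(n_users = n_users, sessions = sessions,
                             duration_s = duration_s, seed = seed)
    value <- list(pop = pop, recs = simulate_cohort(pop, seed = seed))
    cache <<- list(key = key, value = value)
    value
  }
})
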
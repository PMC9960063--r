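test_that("population sampling is seeded and produces valid profiles", {
  p1 <- sample_population(n_users = 5, sessions = 2, duration_s = 40, seed = 7)
  p2 <- sample_population(n_users = 5, sessions = 2, duration_s = 40, seed = 7)
  expect_equal(p1$profiles, p2$profiles)
  expect_equal(p1$durations, p2$durations)
  for (pr in p1$profiles) {
    expect_equal(sum(pr$pref), 1, tolerance = 1e-12)
    M <- transition_matrix(pr, 0.5)
    expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
  # zero perturbation -> identical user preferences
  p0 <- sample_population(n_users = 4, sessions = 1, duration_s = 40,
                          perturb = 0, seed = 3)
  prefs <- vapply(p0$profiles, `[[`, numeric(7), "pref")
  expect_true(all(apply(prefs, 1, function(r) diff(range(r)) == 0)))
})

test_that("simulated recordings respect sampling rate, dwell bounds and gaps", {
  pop <- sample_population(n_users = 2, sessions = 1, duration_s = 60, seed = 2)
  rec <- simulate_recording(pop$profiles[[1]], pop$layout, 60, seed = 2)
  expect_equal(diff(rec$samples$t_ms)[1], 1000 / 120, tolerance = 1e-9)
  expect_true(all(diff(rec$samples$t_ms) > 0))
  expect_true(all(rec$fixations$duration_ms >= 100))
  expect_true(all(rec$fixations$duration_ms <= 3273))
  gaps <- rec$fixations$onset_ms[-1] - rec$fixations$offset_ms[-nrow(rec$fixations)]
  expect_true(all(gaps >= 30 - 1e-9 & gaps <= 80 + 1e-9))
  expect_lte(max(rec$samples$t_ms), rec$duration_ms)
  # same seed -> identical recording
  rec2 <- simulate_recording(pop$profiles[[1]], pop$layout, 60, seed = 2)
  expect_equal(rec$samples, rec2$samples)
  expect_equal(rec$fixations, rec2$fixations)
  expect_equal(rec$truth, rec2$truth)
})

test_that("an absorbing transition matrix pins all later fixations to its AOI", {
  M <- matrix(0, 7, 7)
  M[, 2] <- 1   # every transition goes to AOI 2
  prof <- user_profile(trans = M, noise_px = 0, invalid_rate = 0)
  lay <- default_layout()
  rec <- simulate_recording(prof, lay, 30, seed = 6)
  expect_true(all(rec$truth[-1] == 2))
  hits <- fixation_hits(rec, lay)
  expect_true(all(hits$aoi[rec$truth == 2] == 2))
})

test_that("empirical transitions converge to the profile matrix", {
  base <- c(0.15, 0.25, 0.2, 0.1, 0.1, 0.05, 0.15)
  M <- matrix(rep(base, 7), 7, byrow = TRUE) * 0.4
  diag(M) <- diag(M) + 0.6
  M <- M / rowSums(M)
  prof <- user_profile(trans = M, noise_px = 0, invalid_rate = 0)
  rec <- simulate_recording(prof, default_layout(), 600, seed = 9)
  tr <- table(factor(head(rec$truth, -1), 1:7), factor(rec$truth[-1], 1:7))
  emp <- tr / pmax(rowSums(tr), 1)
  # each well-visited row close to the generator row
  busy <- rowSums(tr) > 100
  expect_true(all(abs(emp[busy, ] - M[busy, ]) < 0.12))
})

test_that("noise-free fixations re-attribute to their generating AOI", {
  pop <- sample_population(n_users = 2, sessions = 1, duration_s = 60,
                           noise_px = 0, invalid_rate = 0, seed = 4)
  # boost pop-up visits so occlusion episodes occur
  prof <- pop$profiles[[1]]
  prof$pref[6] <- 0.25
  prof$pref <- prof$pref / sum(prof$pref)
  rec <- simulate_recording(prof, pop$layout, 90, seed = 4)
  expect_gt(sum(rec$truth == 6), 0)
  hits <- fixation_hits(rec, pop$layout)
  got <- ifelse(is.na(hits$aoi), 7L, hits$aoi)
  expect_equal(got, rec$truth)
})

test_that("cohorts write deterministic per-recording files and a manifest", {
  pop <- sample_population(n_users = 3, sessions = 2, duration_s = 20, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(pop, seed = 8, d1)
  generate_cohort(pop, seed = 8, d2)
  files <- sort(list.files(d1))
  expect_length(grep("_gaze.csv$", files), 6)
  expect_true(all(c("layout.json", "manifest.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man$profiles, 3)
  expect_equal(man$seed, 8)
})

test_that("population heat carries signal for held-out users", {
  ch <- small_cohort()
  lay <- ch$pop$layout
  recs <- lapply(ch$recs, function(r)
    set_fixations(r, filter_short_fixations(r$fixations), "synthetic"))
  labs <- lapply(recs, label_windows, layout = lay, tau_s = 5)
  users <- vapply(recs, `[[`, character(1), "user_id")
  train <- users %in% unique(users)[1:7]
  heat <- lapply(1:12, function(t) heat_aoi(labs[train], t, lay$n_aoi))
  hmat <- do.call(rbind, heat)
  test_rows <- do.call(rbind, lapply(labs[!train], function(Y) Y[1:12, ]))
  hrep <- hmat[rep(1:12, sum(!train)), ]
  expect_gt(cor(as.vector(hrep), as.vector(test_rows)), 0)
})
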
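# Hand-computed fixtures for each feature family, plus the structural and
# causality properties of the assembled design matrix.

test_that("AOI history features match hand computations", {
  lay <- default_layout()
  # last AOI-3 fixation ends at 12 s; window 4 starts at 15 s -> tslv 3 s
  rec <- make_recording(
    fixations = make_fixations(c(3000, 11600, 16000),
                               c(3400, 12000, 16400),
                               c(300, 300, 500), c(300, 950, 400)),
    duration_ms = 21000)
  hits <- fixation_hits(rec, lay)
  expect_equal(hits$aoi, c(2L, 3L, 2L))
  Y <- label_windows(rec, lay, 5)
  f <- aoi_history_features(Y, hits, t = 4, tau_s = 5)
  expect_equal(unname(f["AOI_3_tslv"]), 3)
  expect_equal(unname(f["AOI_2_tslv"]), 11.6)
  # AOI 5 never visited -> tslv 0
  expect_equal(unname(f["AOI_5_tslv"]), 0)
  # previous window (3) ends with the AOI-3 fixation? window 3 = [10,15)s
  # holds fixation 11.6-12 s in AOI 3 -> end_r1 flags and End_r1 = 3
  expect_equal(unname(f["AOI_3_end_r1"]), 1)
  expect_equal(sum(f[grepl("end_r1", names(f))]), 1)
  expect_equal(unname(f["End_r1"]), 3)
  # r-features: AOI 3 active in window 3 -> r1 = 1; not in 2 -> r2 = 0
  expect_equal(unname(f["AOI_3_r1"]), 1)
  expect_equal(unname(f["AOI_3_r2"]), 0)
  # early window: r-lags before the recording are 0
  f2 <- aoi_history_features(Y, hits, t = 2, tau_s = 5)
  expect_equal(unname(f2["AOI_2_r3"]), 0)
})

test_that("component history features match hand computations", {
  lay <- default_layout()
  # two fixations on Banner_1 (660,170)-(960,470) of 200 and 400 ms -> atv 300
  # gaps: fix1 ends 2.0 s, fix2 starts 5.0 s (gap 3.0); fix2 ends 5.2 s,
  # fix3 starts 9.2 s (gap 4.0) -> atbv = 3.5 s = 3500 ms on Logo
  rec <- make_recording(
    fixations = make_fixations(
      onset = c(1500, 3000, 5000, 7000, 9200),
      offset = c(2000, 3200, 5200, 7400, 9500),
      cx = c(100, 700, 100, 700, 100),
      cy = c(40, 300, 40, 300, 40)),
    duration_ms = 16000)
  hits <- fixation_hits(rec, lay)
  expect_equal(hits$component, c("Logo", "Banner_1", "Logo", "Banner_1", "Logo"))
  f <- component_history_features(hits, lay$components$id, t = 3, tau_s = 5)
  expect_equal(unname(f["Banner_1_atv"]), 300)
  expect_equal(unname(f["Logo_atbv"]), 3500)
  expect_equal(unname(f["Logo_his"]), 1)
  expect_equal(unname(f["New_1_his"]), 0)
  expect_equal(unname(f["New_1_tslv"]), 0)
  expect_equal(unname(f["New_1_atv"]), 0)
  expect_equal(unname(f["New_1_atbv"]), 0)
  # window 2 = [5,10)s: last component fixated there is Logo (onset 9.2 s)
  expect_equal(unname(f["Logo_end_r1"]), 1)
  expect_equal(unname(f["Comp_end"]), match("Logo", lay$components$id))
})

test_that("population heat is the training-fold visit frequency", {
  mk <- function(v) matrix(v, nrow = 4, ncol = 2)
  labs <- list(mk(1), mk(0), mk(1), mk(1))
  h <- heat_aoi(labs, t = 3, n_aoi = 2)
  expect_equal(unname(h), c(0.75, 0.75))
  expect_equal(unname(heat_aoi(list(mk(0), mk(0)), 2, 2)), c(0, 0))
  # window index beyond every training recording -> 0
  expect_equal(unname(heat_aoi(labs, t = 9, n_aoi = 2)), c(0, 0))
})

test_that("kinematics recover analytic velocity and acceleration", {
  # constant position
  s0 <- constant_samples(0, 10000, 512, 300)
  f0 <- kinematics_features(s0, t = 2, tau_s = 5)
  expect_equal(unname(f0["coordX"]), 512)
  expect_equal(unname(f0["StdX"]), 0)
  expect_equal(unname(f0["VelX"]), 0)
  expect_equal(unname(f0["AclX"]), 0)

  # linear motion x = 100 t px (t in s): VelX = 100 exactly, AclX ~ 0
  ts <- seq(0, 10000, by = 1000 / 120)
  s1 <- data.frame(t_ms = ts, x_px = 100 * ts / 1000, y_px = 7, valid = TRUE)
  f1 <- kinematics_features(s1, t = 2, tau_s = 5)
  expect_equal(unname(f1["VelX"]), 100, tolerance = 1e-9)
  expect_equal(unname(f1["MeanVelX"]), 100, tolerance = 1e-9)
  expect_lt(abs(f1["AclX"]), 1e-6)

  # quadratic motion x = 50 t^2: AclX = 100 px/s^2 via central differences
  s2 <- data.frame(t_ms = ts, x_px = 50 * (ts / 1000)^2, y_px = 0, valid = TRUE)
  f2 <- kinematics_features(s2, t = 2, tau_s = 5)
  expect_equal(unname(f2["AclX"]), 100, tolerance = 1e-6)
  expect_equal(unname(f2["MeanAclX"]), 100, tolerance = 1e-6)

  # X definitions applied to Y reproduce Y features (symmetry)
  set.seed(9)
  sw <- data.frame(t_ms = ts, x_px = cumsum(rnorm(length(ts))),
                   y_px = cumsum(rnorm(length(ts))), valid = TRUE)
  fx <- kinematics_features(sw, 2, 5)
  swapped <- data.frame(t_ms = ts, x_px = sw$y_px, y_px = sw$x_px, valid = TRUE)
  fy <- kinematics_features(swapped, 2, 5)
  xn <- grep("X$", names(fx), value = TRUE)
  expect_equal(unname(fx[xn]), unname(fy[sub("X$", "Y", xn)]))

  # too few samples -> zeros
  s3 <- data.frame(t_ms = c(0, 10), x_px = 5, y_px = 5, valid = TRUE)
  expect_equal(unname(kinematics_features(s3, 2, 5)["VelX"]), 0)
})

test_that("oculomotor statistics summarize the pre-window history", {
  fx <- make_fixations(c(0, 500, 1000), c(100, 700, 1300), c(0, 300, 0),
                       c(0, 400, 0))
  sc <- derive_saccades(fx)
  f <- oculomotor_features(fx, sc, t = 2, tau_s = 5)
  expect_equal(unname(f["NFix"]), 3)
  expect_equal(unname(f["TPromFix"]), 200)
  expect_equal(unname(f["TMaxFix"]), 300)
  expect_equal(unname(f["TMinFix"]), 100)
  expect_equal(unname(f["NSac"]), 2)
  expect_equal(unname(f["APromSac"]), 500)
  # empty history -> zeros
  f0 <- oculomotor_features(fx[0, ], sc[0, ], t = 2, tau_s = 5)
  expect_true(all(f0 == 0))
})

test_that("design matrices have stable registries and drop window 1", {
  ch <- small_cohort()
  lay <- ch$pop$layout
  recs <- lapply(ch$recs[1:8], function(r)
    set_fixations(r, filter_short_fixations(r$fixations), "synthetic"))
  ex <- lapply(recs, extract_features, layout = lay, tau_s = 5)
  # 60 s recordings: 12 windows -> 11 instances each
  expect_true(all(vapply(ex, function(e) nrow(e$X), integer(1)) == 11))
  expect_true(all(vapply(ex, function(e) all(e$keys$window >= 2), logical(1))))
  reg <- feature_registry(lay)
  C <- nrow(lay$components)
  expect_length(reg, (5 * 6 + 1) + (5 * C + 1) + 6 + 18 + 8)
  users <- unique(vapply(recs, `[[`, character(1), "user_id"))
  P <- setNames(rep(12 * 2, 4), users)
  fa <- assign_folds(P, K = 2)
  dm <- build_design_matrix(recs, lay, 5, fa, k = 1, extracted = ex)
  expect_identical(colnames(dm$train$X), reg)
  expect_identical(colnames(dm$test$X), reg)
  expect_false(anyNA(dm$train$X))
  heat <- dm$train$X[, grep("^Heat_", reg)]
  expect_true(all(heat >= 0 & heat <= 1))
  # different test folds change Heat columns only
  dm2 <- build_design_matrix(recs, lay, 5, fa, k = 2, extracted = ex)
  base_cols <- setdiff(reg, grep("^Heat_", reg, value = TRUE))
  both <- intersect(paste(dm$test$keys$user, dm$test$keys$session,
                          dm$test$keys$window),
                    paste(dm2$train$keys$user, dm2$train$keys$session,
                          dm2$train$keys$window))
  i1 <- match(both, paste(dm$test$keys$user, dm$test$keys$session,
                          dm$test$keys$window))
  i2 <- match(both, paste(dm2$train$keys$user, dm2$train$keys$session,
                          dm2$train$keys$window))
  expect_equal(dm$test$X[i1, base_cols], dm2$train$X[i2, base_cols])
})

test_that("features are causal and blind to the test fold", {
  ch <- small_cohort()
  lay <- ch$pop$layout
  recs <- lapply(ch$recs, function(r)
    set_fixations(r, filter_short_fixations(r$fixations), "synthetic"))
  ex <- lapply(recs, extract_features, layout = lay, tau_s = 5)
  users <- vapply(recs, `[[`, character(1), "user_id")
  P <- tapply(vapply(ex, function(e) nrow(e$labels), integer(1)), users, sum)
  fa <- assign_folds(P[unique(users)], K = 5)
  dm <- build_design_matrix(recs, lay, 5, fa, k = 1, extracted = ex)
  test_users <- names(fa$fold)[fa$fold == 1]
  u <- test_users[1]
  # target instance: this user's first recording, window 6
  ri <- which(users == u)[1]
  t0 <- 6
  To <- (t0 - 1) * 5000
  row_full <- dm$test$X[dm$test$keys$user == u &
                          dm$test$keys$session == recs[[ri]]$session_id &
                          dm$test$keys$window == t0, ]

  # ablate user u's data at times >= To in every one of their recordings
  ablate <- function(r) {
    r$samples <- r$samples[r$samples$t_ms < To, , drop = FALSE]
    fx <- r$fixations[r$fixations$onset_ms < To, c("onset_ms", "offset_ms",
                                                   "cx_px", "cy_px")]
    r$events <- r$events[r$events$t_ms < To, , drop = FALSE]
    set_fixations(r, fx, "synthetic")
  }
  recs_abl <- recs
  for (i in which(users == u)) recs_abl[[i]] <- ablate(recs_abl[[i]])
  # and delete every other test-fold user entirely
  keep <- users == u | !(users %in% test_users)
  recs_abl <- recs_abl[keep]
  ex_abl <- lapply(recs_abl, extract_features, layout = lay, tau_s = 5)
  fa_abl <- fa
  fa_abl$fold <- fa$fold[names(fa$fold) %in%
                           vapply(recs_abl, `[[`, character(1), "user_id")]
  dm_abl <- build_design_matrix(recs_abl, lay, 5, fa_abl, k = 1,
                                extracted = ex_abl)
  keys_abl <- dm_abl$test$keys
  row_abl <- dm_abl$test$X[keys_abl$user == u &
                             keys_abl$session == recs[[ri]]$session_id &
                             keys_abl$window == t0, ]
  expect_identical(row_full, row_abl)
})
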
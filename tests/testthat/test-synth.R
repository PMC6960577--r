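test_that("the flight schedule has seven contiguous tasks covering the session", {
  sch <- default_schedule(600)
  expect_identical(sch$task, FLIGHT_TASKS)
  expect_equal(nrow(sch), 7L)
  expect_true(all(sch$t_end > sch$t_start))
  expect_equal(sch$t_start[-1], sch$t_end[-7], tolerance = 1e-12)
  expect_equal(sch$t_start[1], 0)
  expect_equal(sch$t_end[7], 600)
  expect_error(default_schedule(-1), "positive")
})

test_that("latent process is degenerate-zero, deterministic and bounded", {
  cfg0 <- small_cfg(task_emotion_means = matrix(0, 5, 7), ou_sigma = 0)
  sch <- default_schedule(cfg0$session_duration)
  lat <- latent_emotion_process(sch, cfg0, seed = 3L)
  expect_true(all(lat == 0))

  cfg <- small_cfg()
  a <- latent_emotion_process(sch, cfg, seed = 5L)
  b <- latent_emotion_process(sch, cfg, seed = 5L)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_false(anyNA(a))
  expect_identical(colnames(a), EMOTIONS)

  expect_error(latent_emotion_process(NULL, cfg, 1L), "no tasks")
  expect_error(
    latent_emotion_process(sch[1:3, ], cfg, 1L), "7 flight tasks")
})

test_that("per-task latent means approach the configured mixture means", {
  means <- matrix(0.3, 5, 7, dimnames = list(EMOTIONS, FLIGHT_TASKS))
  means["surprised", "takeoff"] <- 0.8
  cfg <- small_cfg(task_emotion_means = means)
  sch <- default_schedule(cfg$session_duration)
  takeoff_idx <- which((seq_len(cfg$session_duration * cfg$fs$face) - 1) /
                         cfg$fs$face < sch$t_end[1])
  per_session <- vapply(1:10, function(s) {
    lat <- latent_emotion_process(sch, cfg, seed = 100L + s)
    mean(lat[takeoff_idx, "surprised"])
  }, numeric(1))
  mc_sd <- sd(per_session) / sqrt(length(per_session))
  expect_lt(abs(mean(per_session) - 0.8), 3 * mc_sd + 0.01)
})

test_that("generated sessions have device-style shapes and bounded faces", {
  cfg <- synth_config(n_flights = 2L, session_duration = 60,
                      fs = list(hr = 1, gsr = 16, eeg = 500, face = 30),
                      rng_seed = 2L)
  s <- generate_session(cfg, "RC1")
  expect_s3_class(s, "flight_session")
  expect_length(s$eeg, 8L)
  expect_identical(names(s$eeg), EEG_CHANNELS)
  expect_equal(length(s$eeg$Fp1$values), 30000L)   # 500 Hz x 60 s
  expect_equal(length(s$hr$values), 60L)
  expect_true(all(s$face >= 0 & s$face <= 1))
  expect_true(all(s$latent >= 0 & s$latent <= 1))
  expect_false(anyNA(s$face))
  expect_equal(ts_duration(s$hr), ts_duration(s$gsr))
  bad <- cfg; bad$session_duration <- -5
  expect_error(generate_session(bad, "X"), "duration")
})

test_that("EEG beta power tracks the latent intensities when coupled", {
  cfg <- small_cfg(eeg_beta_power_gain = 12, noise = list(hr = 0.4,
                                                          gsr = 0.01,
                                                          eeg = 1))
  s <- generate_session(cfg, "CPL")
  # independent band-power oracle: periodogram mass in 12-30 Hz per window
  fs <- cfg$fs$eeg
  win <- fs * 5
  n_win <- floor(length(s$eeg$Fp1$values) / win)
  bp <- vapply(seq_len(n_win), function(w) {
    seg <- s$eeg$Fp1$values[((w - 1) * win + 1):(w * win)]
    sp <- stats::spec.pgram(stats::ts(seg, frequency = fs), plot = FALSE,
                            taper = 0)
    sum(sp$spec[sp$freq >= 12 & sp$freq <= 30])
  }, numeric(1))
  load <- as.numeric(s$latent %*% affectflight:::.eeg_loadings()["Fp1", ])
  lat_w <- vapply(seq_len(n_win), function(w) {
    i0 <- floor((w - 1) * 5 * cfg$fs$face) + 1
    mean(load[i0:min(length(load), i0 + 5 * cfg$fs$face - 1)])
  }, numeric(1))
  expect_gt(cor(bp, lat_w, method = "spearman"), 0.3)
})

test_that("zero coupling leaves the modalities independent of the latent trace", {
  cfg <- small_cfg(hr_variability_gain = 0, gsr_peak_rate_gain = 0,
                   eeg_beta_power_gain = 0)
  s <- generate_session(cfg, "DEC")
  arousal <- s$latent[, "scared"] + s$latent[, "surprised"]
  # windowed HR dispersion vs windowed arousal over 12 windows of 5 s
  hr_disp <- vapply(1:12, function(w)
    sd(s$hr$values[((w - 1) * 5 + 1):(w * 5)]), numeric(1))
  ar_w <- vapply(1:12, function(w)
    mean(arousal[((w - 1) * 150 + 1):(w * 150)]), numeric(1))
  expect_lt(abs(cor(hr_disp, ar_w)), 0.75)   # small sample, wide MC band
})

test_that("cohorts are sized, distinct and reproducible", {
  cfg <- small_cfg()
  co <- generate_cohort(cfg)
  expect_length(co, 2L)
  expect_false(anyDuplicated(names(co)) > 0)

  cfg13 <- synth_config(n_flights = 13L, session_duration = 30,
                        fs = list(hr = 2, gsr = 16, eeg = 80, face = 30),
                        rng_seed = 9L)
  co13 <- generate_cohort(cfg13)
  expect_length(co13, 13L)

  co2 <- generate_cohort(cfg)
  expect_identical(co$S01$hr$values, co2$S01$hr$values)
  expect_identical(co$S02$face, co2$S02$face)

  expect_error(generate_cohort(cfg, session_ids = c("A", "A")), "duplicate")
  expect_error(synth_config(n_flights = 1L), "n_flights")
})

test_that("per-session seeds derive stably from the session id", {
  expect_identical(affectflight:::session_seed(1L, "RC1"),
                   affectflight:::session_seed(1L, "RC1"))
  expect_false(affectflight:::session_seed(1L, "RC1") ==
                 affectflight:::session_seed(1L, "RC2"))
  expect_false(affectflight:::session_seed(1L, "RC1") ==
                 affectflight:::session_seed(2L, "RC1"))
})
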
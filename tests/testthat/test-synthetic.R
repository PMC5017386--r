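test_that("default templates are deterministic and cover all nine gestures", {
  t1 <- default_templates(1.0, seed = 7)
  t2 <- default_templates(1.0, seed = 7)
  expect_identical(t1, t2)
  expect_identical(sort(as.character(t1$label)), sort(gesture_codes()))
  expect_equal(nrow(t1), 9)
  # activation patterns nonnegative, motion frequencies in (0, 10]
  expect_true(all(vapply(t1$emg_activation, function(a) all(a >= 0), logical(1))))
  expect_true(all(t1$motion_freq > 0 & t1$motion_freq <= 10))
  # motion axes are unit vectors
  expect_true(all(vapply(t1$motion_axis,
                         function(ax) max(abs(rowSums(ax^2) - 1)) < 1e-12,
                         logical(1))))
})

test_that("separation scales inter-template distance", {
  d_hi <- template_min_distance(default_templates(1.0, seed = 7))
  d_lo <- template_min_distance(default_templates(0.1, seed = 7))
  expect_gt(d_hi, d_lo)
  expect_error(default_templates(0), class = "handwashr_validation_error")
  expect_error(default_templates(1.5), class = "handwashr_validation_error")
})

test_that("a default-length session has 9000 EMG and 2250 IMU rows per arm", {
  s <- make_sim_session(dur_s = 5)
  expect_equal(dim(s$left$emg), c(9000, 8))
  expect_equal(dim(s$right$imu), c(2250, 10))
  expect_equal(n_frames(s), 2250)
  # labels appear in routine order with equal frame counts
  expect_identical(as.character(unique(s$labels)), gesture_codes())
  expect_true(all(table(s$labels) == 250))
})

test_that("simulation is deterministic and gesture segments carry constant labels", {
  s1 <- make_sim_session(dur_s = 1, seed = 5)
  s2 <- make_sim_session(dur_s = 1, seed = 5)
  expect_identical(s1$left$emg, s2$left$emg)
  expect_identical(s1$right$imu, s2$right$imu)
  expect_identical(s1$labels, s2$labels)
})

test_that("zero activation and zero noise floor give identically zero EMG", {
  cfg <- sim_config(n_subjects = 1, n_repetitions = 1, gesture_duration_s = 1,
                    seed = 3, noise_floor = 0)
  tpl <- default_templates(1.0, seed = 3)
  tpl$emg_activation <- lapply(tpl$emg_activation, function(a) a * 0)
  prof <- subject_profiles(cfg, seed = 4)
  prof$noise_floor <- 0
  s <- simulate_session(tpl, prof[1, ], cfg, repetition = 1, seed = 5)
  expect_true(all(s$left$emg == 0))
  expect_true(all(s$right$emg == 0))
})

test_that("segment EMG RMS tracks gain x template RMS within 10%", {
  cfg <- sim_config(n_subjects = 1, n_repetitions = 1, gesture_duration_s = 5,
                    seed = 9, noise_floor = 0)
  tpl <- default_templates(1.0, seed = 9)
  prof <- subject_profiles(cfg, seed = 10)
  prof$noise_floor <- 0
  s <- simulate_session(tpl, prof[1, ], cfg, repetition = 1, seed = 11)
  gains <- prof$channel_gain[[1]]
  seg <- rep(1:9, each = 1000)
  for (g in c(1, 4, 9)) {
    target <- gains * tpl$emg_activation[[g]]   # placement angle is 0 in rep 1
    for (arm in 1:2) {
      emg <- if (arm == 1) s$left$emg else s$right$emg
      rms <- sqrt(colMeans(emg[seg == g, ]^2))
      expect_true(all(abs(rms / target[arm, ] - 1) < 0.10))
    }
  }
})

test_that("EMG stays in int8 range with a clipping rate below 1%", {
  s <- make_sim_session(dur_s = 5, seed = 13)
  emg <- rbind(s$left$emg, s$right$emg)
  expect_true(all(emg >= -128 & emg <= 127))
  clip_rate <- mean(emg >= 127 | emg <= -128)
  expect_lt(clip_rate, 0.01)
})

test_that("channel mixing rotates by whole and fractional electrode steps", {
  act <- rbind(1:8, 8:1)
  expect_equal(mix_channels(act, 0), act)
  # one full electrode spacing: circular shift by one channel
  expect_equal(mix_channels(act, 2 * pi / 8)[1, ], c(2:8, 1))
  # half spacing: average of adjacent channels
  expect_equal(mix_channels(act, pi / 8)[1, ], (c(1:8) + c(2:8, 1)) / 2)
})

test_that("cohorts write n_subjects x n_repetitions sessions deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 2, n_repetitions = 2, gesture_duration_s = 1,
                    seed = 17)
  man1 <- simulate_cohort(cfg, d1)
  expect_length(man1$sessions, 4)
  expect_length(man1$subjects, 2)
  expect_true(all(dir.exists(manifest_sessions(man1))))
  man2 <- simulate_cohort(cfg, d2)
  expect_identical(man1$sessions, man2$sessions)
  for (f in c("left_emg.csv", "right_imu.csv", "labels.csv")) {
    expect_identical(readLines(file.path(d1, man1$sessions[1], f)),
                     readLines(file.path(d2, man2$sessions[1], f)))
  }
  # single-session cohort
  man3 <- make_sim_cohort(n_subjects = 1, n_repetitions = 1, dur_s = 1)
  expect_length(man3$sessions, 1)
})

test_that("placement angle is zero in the first repetition and bounded afterwards", {
  cfg <- sim_config(n_subjects = 5, n_repetitions = 3, seed = 23)
  prof <- subject_profiles(cfg)
  for (i in 1:5) {
    ang <- prof$placement_angles[[i]]
    expect_length(ang, 3)
    expect_identical(ang[1], 0)
    expect_true(all(abs(ang) <= cfg$placement_max_angle))
  }
})
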
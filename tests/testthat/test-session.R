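test_that("stream invariants are enforced", {
  good <- make_zero_stream(1)
  expect_s3_class(good, "armband_stream")

  emg_bad <- good$emg; emg_bad[5, 2] <- 300
  expect_error(armband_stream(emg_bad, good$imu), "int8",
               class = "handwashr_validation_error")

  # EMG/IMU lengths disagreeing by more than one IMU frame
  expect_error(armband_stream(good$emg[1:100, ], good$imu),
               "durations disagree", class = "handwashr_validation_error")

  imu_bad <- good$imu; imu_bad[3, 1] <- 0.9
  expect_error(armband_stream(good$emg, imu_bad), "quaternion",
               class = "handwashr_validation_error")
})

test_that("arms with IMU lengths differing by one frame are truncated to the minimum", {
  left <- make_zero_stream(1)
  right <- make_zero_stream(1)
  right$imu <- right$imu[1:49, ]
  right$emg <- right$emg[1:196, ]
  s <- session_recording(left, right, labels = rep("G1", 49),
                         subject_id = "T", repetition = 1)
  expect_equal(nrow(s$left$imu), 49)
  expect_equal(nrow(s$right$imu), 49)
  expect_equal(n_frames(s), 49)
})

test_that("a 5 s single-gesture session writes 1000 EMG and 250 IMU data rows", {
  dir <- withr::local_tempdir()
  write_session(make_zero_session("G1", dur_s = 5), dir)
  expect_length(readLines(file.path(dir, "left_emg.csv")), 1000 + 1)
  expect_length(readLines(file.path(dir, "left_imu.csv")), 250 + 1)
  expect_identical(readLines(file.path(dir, "left_emg.csv"), n = 1),
                   paste(c("t", paste0("ch", 1:8)), collapse = ","))
})

test_that("a 9-gesture x 5 s session has 2250 label rows on disk", {
  dir <- withr::local_tempdir()
  write_session(make_zero_session(gesture_codes(), dur_s = 5), dir)
  expect_length(readLines(file.path(dir, "labels.csv")), 2250 + 1)
})

test_that("write/read round-trips a simulated session", {
  s <- make_sim_session(dur_s = 1)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_identical(unname(s2$left$emg), unname(s$left$emg))   # ints bit-exact
  expect_identical(unname(s2$right$emg), unname(s$right$emg))
  expect_equal(unname(s2$left$imu), unname(s$left$imu), tolerance = 1e-9)
  expect_identical(as.character(s2$labels), as.character(s$labels))
  expect_identical(s2$subject_id, s$subject_id)
  expect_identical(s2$repetition, s$repetition)
})

test_that("reading rejects corrupt sessions with file- and row-level messages", {
  s <- make_zero_session(gesture_codes(), dur_s = 1)
  dir <- withr::local_tempdir()
  write_session(s, dir)

  # out-of-range EMG value in a named row
  emg_path <- file.path(dir, "left_emg.csv")
  lines <- readLines(emg_path)
  lines[6] <- sub(",0,", ",300,", lines[6])   # data row 5
  writeLines(lines, emg_path)
  expect_error(read_session(dir), "left_emg.csv row 5",
               class = "handwashr_validation_error")
  write_session(s, dir)

  # unknown gesture label
  lab_path <- file.path(dir, "labels.csv")
  lines <- readLines(lab_path)
  lines[3] <- "1,G7"
  writeLines(lines, lab_path)
  expect_error(read_session(dir), "G7", class = "handwashr_validation_error")
  write_session(s, dir)

  # missing file
  file.remove(file.path(dir, "right_imu.csv"))
  expect_error(read_session(dir), "right_imu",
               class = "handwashr_validation_error")
})

test_that("manifests round-trip and validate listed paths", {
  dir <- withr::local_tempdir()
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 1, dur_s = 1,
                         dir = dir)
  man2 <- read_manifest(dir)
  expect_identical(man2$sessions, man$sessions)
  expect_identical(man2$subjects, man$subjects)
  unlink(manifest_sessions(man)[1], recursive = TRUE)
  expect_error(read_manifest(dir), "missing session",
               class = "handwashr_validation_error")
})
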
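#' @keywords internal
EMG_RATE <- 200L   # Hz, 8 int8 channels per armband
#' @keywords internal
IMU_RATE <- 50L    # Hz, 10 float channels per armband

IMU_CHANNELS <- c("qw", "qx", "qy", "qz", "ax", "ay", "az", "gx", "gy", "gz")
SCHEMA_VERSION <- "1.0"

#' Construct a single-armband stream
#'
#' One armband emits an 8-channel surface-EMG stream at 200 Hz with int8
#' samples, and a 10-channel IMU stream at 50 Hz: an orientation quaternion
#' (`qw, qx, qy, qz`), linear acceleration (`ax, ay, az`, m/s^2) and angular
#' velocity (`gx, gy, gz`, rad/s). Both streams must cover the same
#' wall-clock duration to within one IMU frame, quaternion rows must have
#' unit norm (within 1e-3), and EMG samples must fit the int8 range.
#'
#' @param emg Numeric matrix `[n_emg x 8]` of integer-valued samples in
#'   `[-128, 127]`.
#' @param imu Numeric matrix `[n_imu x 10]` with columns in the order
#'   `qw, qx, qy, qz, ax, ay, az, gx, gy, gz`.
#' @param t0 Shared stream start time in seconds.
#' @return An `armband_stream` object.
#' @export
armband_stream <- function(emg, imu, t0 = 0) {
  emg <- as.matrix(emg)
  imu <- as.matrix(imu)
  stream <- structure(list(emg = emg, imu = imu, t0 = as.numeric(t0)),
                      class = "armband_stream")
  stream <- validate_armband_stream(stream)
  storage.mode(stream$emg) <- "integer"   # canonical int8-valued storage
  storage.mode(stream$imu) <- "double"
  stream
}

validate_armband_stream <- function(stream, context = "armband stream") {
  emg <- stream$emg
  imu <- stream$imu
  fail <- function(msg, ...) {
    abort(sprintf(paste0(context, ": ", msg), ...),
          class = "handwashr_validation_error")
  }
  if (ncol(emg) != 8) fail("EMG must have 8 channels, got %d", ncol(emg))
  if (ncol(imu) != 10) fail("IMU must have 10 channels, got %d", ncol(imu))
  if (anyNA(emg) || anyNA(imu)) fail("streams must not contain NA")
  rng <- range(emg)
  if (rng[1] < -128 || rng[2] > 127) {
    idx <- which(emg < -128 | emg > 127, arr.ind = TRUE)[1, ]
    fail("EMG value %g at row %d, column %d outside int8 range [-128, 127]",
         emg[idx[1], idx[2]], idx[1], idx[2])
  }
  if (any(emg != round(emg))) fail("EMG samples must be integer-valued")
  # both streams must describe the same wall-clock duration
  if (abs(nrow(emg) / EMG_RATE - nrow(imu) / IMU_RATE) > 1 / IMU_RATE + 1e-9) {
    fail("EMG (%d samples @ %d Hz) and IMU (%d samples @ %d Hz) durations disagree by more than one IMU frame",
         nrow(emg), EMG_RATE, nrow(imu), IMU_RATE)
  }
  qnorm2 <- sqrt(rowSums(imu[, 1:4, drop = FALSE]^2))
  if (any(abs(qnorm2 - 1) > 1e-3)) {
    fail("quaternion row %d has norm %.6f (must be 1 within 1e-3)",
         which(abs(qnorm2 - 1) > 1e-3)[1], qnorm2[which(abs(qnorm2 - 1) > 1e-3)[1]])
  }
  stream
}

#' @export
print.armband_stream <- function(x, ...) {
  cat(sprintf("<armband_stream> %d EMG samples @ %d Hz, %d IMU frames @ %d Hz, t0 = %g s\n",
              nrow(x$emg), EMG_RATE, nrow(x$imu), IMU_RATE, x$t0))
  invisible(x)
}

#' Construct a dual-armband session recording
#'
#' A session is one subject performing one repetition of the full WHO
#' routine: a left and a right [armband_stream()] plus a gesture label track
#' defined at the IMU frame rate (50 Hz). If the two arms' IMU lengths
#' differ (by at most one frame), both are truncated to the shorter.
#'
#' @param left,right [armband_stream()] objects.
#' @param labels Character vector or factor of gesture codes, one per IMU
#'   frame (see [gesture_codes()]).
#' @param subject_id Subject identifier string.
#' @param repetition Repetition number (>= 1).
#' @return A `session_recording` object.
#' @export
session_recording <- function(left, right, labels, subject_id, repetition = 1L) {
  stopifnot(inherits(left, "armband_stream"), inherits(right, "armband_stream"))
  n <- min(nrow(left$imu), nrow(right$imu))
  trunc_stream <- function(s, n) {
    s$imu <- s$imu[seq_len(n), , drop = FALSE]
    ne <- min(nrow(s$emg), n * (EMG_RATE / IMU_RATE))
    s$emg <- s$emg[seq_len(ne), , drop = FALSE]
    s
  }
  left <- trunc_stream(left, n)
  right <- trunc_stream(right, n)
  labels <- gesture_factor(labels)
  if (length(labels) != n) {
    abort(sprintf("label track has %d frames but the session has %d IMU frames",
                  length(labels), n),
          class = "handwashr_validation_error")
  }
  if (repetition < 1) abort("repetition must be >= 1",
                            class = "handwashr_validation_error")
  structure(list(left = left, right = right, labels = labels,
                 subject_id = as.character(subject_id),
                 repetition = as.integer(repetition)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s, repetition %d: %d frames (%.1f s), gestures %s\n",
              x$subject_id, x$repetition, n_frames(x), n_frames(x) / IMU_RATE,
              paste(unique(as.character(x$labels)), collapse = " ")))
  invisible(x)
}

#' @rdname session_recording
#' @param session A `session_recording`.
#' @return `n_frames()` returns the number of 50 Hz frames in the session.
#' @export
n_frames <- function(session) {
  length(session$labels)
}

fmt_time <- function(n, rate, t0) {
  sprintf("%.6f", t0 + (seq_len(n) - 1) / rate)
}

#' Write a session recording to a directory
#'
#' The on-disk format is plain CSV plus a JSON meta file, so recordings are
#' human-inspectable and diff-able: `meta.json` (subject, repetition, t0,
#' schema version), `left_emg.csv`/`right_emg.csv` with header `t,ch1..ch8`
#' (time in seconds to 6 decimals, integer channel values),
#' `left_imu.csv`/`right_imu.csv` with header `t,qw,qx,qy,qz,ax,ay,az,gx,gy,gz`,
#' and `labels.csv` with header `frame,label` (0-based frames).
#'
#' @param session A [session_recording()].
#' @param dir Directory to create/write into.
#' @return The directory path, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create session directory '%s'", dir),
          class = "handwashr_io_error")
  }
  write_stream <- function(stream, side) {
    emg <- as.data.frame(matrix(as.integer(stream$emg), nrow(stream$emg)))
    names(emg) <- paste0("ch", 1:8)
    emg <- cbind(data.frame(t = fmt_time(nrow(emg), EMG_RATE, stream$t0)), emg)
    data.table::fwrite(emg, file.path(dir, paste0(side, "_emg.csv")))
    imu <- as.data.frame(stream$imu)
    names(imu) <- IMU_CHANNELS
    imu <- cbind(data.frame(t = fmt_time(nrow(imu), IMU_RATE, stream$t0)), imu)
    data.table::fwrite(imu, file.path(dir, paste0(side, "_imu.csv")))
  }
  write_stream(session$left, "left")
  write_stream(session$right, "right")
  data.table::fwrite(
    data.table::data.table(frame = seq_along(session$labels) - 1L,
                           label = as.character(session$labels)),
    file.path(dir, "labels.csv"))
  jsonlite::write_json(
    list(subject_id = session$subject_id,
         repetition = session$repetition,
         t0 = session$left$t0,
         schema_version = SCHEMA_VERSION),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_csv_checked <- function(path, expected_header) {
  if (!file.exists(path)) {
    abort(sprintf("missing session file '%s'", path),
          class = "handwashr_validation_error")
  }
  dt <- data.table::fread(path, colClasses = list(numeric = expected_header[1]))
  if (!identical(names(dt), expected_header)) {
    abort(sprintf("malformed header in '%s': expected '%s', got '%s'",
                  basename(path), paste(expected_header, collapse = ","),
                  paste(names(dt), collapse = ",")),
          class = "handwashr_validation_error")
  }
  dt
}

#' Read a session recording from a directory
#'
#' Reads and validates the six files written by [write_session()]; any
#' invariant violation (unknown gesture code, EMG value outside int8,
#' inconsistent stream durations, non-unit quaternions) raises a validation
#' error naming the offending file and row.
#'
#' @param dir Session directory.
#' @return A validated [session_recording()].
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("missing session file '%s'", meta_path),
          class = "handwashr_validation_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  read_stream <- function(side) {
    emg_file <- paste0(side, "_emg.csv")
    emg <- read_csv_checked(file.path(dir, emg_file), c("t", paste0("ch", 1:8)))
    emat <- as.matrix(emg[, -1])
    bad <- which(emat < -128 | emat > 127, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("%s row %d column %s: EMG value %g outside int8 range",
                    emg_file, bad[1, 1], colnames(emat)[bad[1, 2]],
                    emat[bad[1, 1], bad[1, 2]]),
            class = "handwashr_validation_error")
    }
    imu <- read_csv_checked(file.path(dir, paste0(side, "_imu.csv")),
                            c("t", IMU_CHANNELS))
    armband_stream(emat, as.matrix(imu[, -1]), t0 = meta$t0)
  }
  left <- read_stream("left")
  right <- read_stream("right")
  lab <- read_csv_checked(file.path(dir, "labels.csv"), c("frame", "label"))
  session_recording(left, right, lab$label,
                    subject_id = meta$subject_id,
                    repetition = meta$repetition)
}

#' Dataset manifests
#'
#' A manifest lists the session directories making up a cohort, with paths
#' stored relative to the manifest location. [simulate_cohort()] writes one;
#' [read_manifest()] loads it back and [manifest_sessions()] resolves the
#' absolute session paths.
#'
#' @param sessions Character vector of session directory paths (relative to
#'   `root`).
#' @param subjects Character vector of subject ids.
#' @param root Directory the paths are relative to.
#' @return A `dataset_manifest` object.
#' @export
dataset_manifest <- function(sessions, subjects, root = ".") {
  structure(list(sessions = as.character(sessions),
                 subjects = as.character(subjects),
                 schema_version = SCHEMA_VERSION,
                 root = normalizePath(root, mustWork = FALSE)),
            class = "dataset_manifest")
}

#' @rdname dataset_manifest
#' @param manifest A `dataset_manifest`.
#' @export
manifest_sessions <- function(manifest) {
  file.path(manifest$root, manifest$sessions)
}

#' @rdname dataset_manifest
#' @export
write_manifest <- function(manifest, dir) {
  jsonlite::write_json(
    list(sessions = manifest$sessions, subjects = manifest$subjects,
         schema_version = manifest$schema_version),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname dataset_manifest
#' @param dir Directory containing `manifest.json`.
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  man <- dataset_manifest(m$sessions, m$subjects, root = dir)
  missing <- !dir.exists(manifest_sessions(man))
  if (any(missing)) {
    abort(sprintf("manifest lists missing session directories: %s",
                  paste(m$sessions[missing], collapse = ", ")),
          class = "handwashr_validation_error")
  }
  man
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d sessions, %d subjects (schema %s)\n",
              length(x$sessions), length(x$subjects), x$schema_version))
  invisible(x)
}
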
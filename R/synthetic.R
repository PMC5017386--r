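#' Simulation configuration for a synthetic dual-armband cohort
#'
#' Defaults mirror the acquisition protocol the package targets: 17
#' subjects, each performing the nine-gesture WHO routine three times, every
#' gesture held for 5 s, with the armbands slightly re-seated (rotated)
#' between repetitions.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param n_repetitions Routine repetitions per subject (default 3).
#' @param gesture_duration_s Seconds each gesture is held (default 5).
#' @param seed Integer seed; the whole cohort is a pure function of this
#'   configuration.
#' @param separation Inter-gesture template distance scaling in (0, 1]; 1 is
#'   the nominal, well-separated gesture set, smaller values blend all
#'   templates toward their mean and make the recognition task harder.
#' @param placement_max_angle Maximum armband rotation offset (radians)
#'   drawn per repetition; default `pi/8`, half the 45 degree spacing of the
#'   8 EMG electrodes.
#' @param gain_sdlog Log-sd of the per-subject, per-channel lognormal EMG
#'   gains (inter-subject variability placeholder).
#' @param noise_floor Additive EMG noise floor, RMS units.
#' @param emg_base,emg_peak Baseline and peak template activation (EMG RMS
#'   units) of the per-channel activation bumps.
#' @param acc_noise_sd,gyro_noise_sd IMU additive noise standard deviations
#'   (m/s^2 and rad/s).
#' @param crossfade_s Optional linear cross-fade (seconds) of EMG amplitude
#'   between adjacent gestures; 0 (default) records each gesture in
#'   isolation, as in the protocol being emulated.
#' @return A `sim_config` object (a named list).
#' @export
sim_config <- function(n_subjects = 17L, n_repetitions = 3L,
                       gesture_duration_s = 5, seed = 1L,
                       separation = 1, placement_max_angle = pi / 8,
                       gain_sdlog = 0.25, noise_floor = 1,
                       emg_base = 6, emg_peak = 18,
                       acc_noise_sd = 0.05, gyro_noise_sd = 0.5,
                       crossfade_s = 0) {
  if (n_subjects < 1 || n_repetitions < 1) {
    abort("n_subjects and n_repetitions must be >= 1",
          class = "handwashr_validation_error")
  }
  if (gesture_duration_s <= 0) {
    abort("gesture_duration_s must be > 0", class = "handwashr_validation_error")
  }
  if (separation <= 0 || separation > 1) {
    abort("separation must be in (0, 1]", class = "handwashr_validation_error")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_repetitions = as.integer(n_repetitions),
                 gesture_duration_s = gesture_duration_s,
                 seed = as.integer(seed),
                 separation = separation,
                 placement_max_angle = placement_max_angle,
                 gain_sdlog = gain_sdlog,
                 noise_floor = noise_floor,
                 emg_base = emg_base, emg_peak = emg_peak,
                 acc_noise_sd = acc_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 crossfade_s = crossfade_s),
            class = "sim_config")
}

# circular von-Mises-like bump over the 8 electode positions
channel_bump <- function(center, width = 1.1) {
  ch <- 0:7
  d <- pmin(abs(ch - center), 8 - abs(ch - center))
  exp(-0.5 * (d / width)^2)
}

#' Default gesture templates
#'
#' Builds one synthetic activation template per WHO gesture: a smooth bump
#' of muscle activation over the 8 electrode positions of each armband (the
#' leading arm of L/R gestures is emphasised), plus a per-gesture arm motion
#' (rotation axis, frequency and amplitude) driving the IMU channels.
#' `separation` blends all templates toward their common mean, so 1 gives
#' the nominal well-separated set and small values make gestures nearly
#' indistinguishable.
#'
#' @param separation Template distance scaling in (0, 1].
#' @param seed Integer seed for the template jitter.
#' @param min_cos_dist Minimum pairwise cosine distance between flattened
#'   activation patterns, at `separation = 1`; the generated set is checked
#'   against `min_cos_dist * separation^2`.
#' @return A tibble with one row per gesture: `label`, `emg_activation`
#'   (list of 2 x 8 matrices, rows = left/right arm), `motion_axis` (list of
#'   2 x 3 matrices of unit vectors), `motion_freq` (Hz), `motion_amp`
#'   (radians).
#' @export
default_templates <- function(separation = 1, seed = 7L, min_cos_dist = 0.02) {
  if (separation <= 0 || separation > 1) {
    abort("separation must be in (0, 1]", class = "handwashr_validation_error")
  }
  codes <- gesture_codes()
  withr::with_seed(seed, {
    acts <- lapply(0:8, function(o) {
      code <- codes[o + 1]
      lead <- if (grepl("L$", code)) "left" else if (grepl("R$", code)) "right" else "both"
      emph <- switch(lead, both = c(1, 1), left = c(1.3, 0.8), right = c(0.8, 1.3))
      centers <- c((o * 8 / 9) %% 8, ((o * 3 + 2) * 8 / 9) %% 8)
      jit <- matrix(exp(rnorm(16, sd = 0.1)), 2, 8)
      act <- rbind(6 + 18 * emph[1] * channel_bump(centers[1]),
                   6 + 18 * emph[2] * channel_bump(centers[2])) * jit
      act
    })
    axes <- lapply(0:8, function(o) {
      a <- 2 * pi * o / 9
      ax_l <- c(cos(a), sin(a), 0.5)
      ax_r <- c(cos(a + 0.7), sin(a + 0.7), -0.5)
      rbind(ax_l / sqrt(sum(ax_l^2)), ax_r / sqrt(sum(ax_r^2)))
    })
  })
  freqs <- 0.8 + 0.25 * (0:8)
  amps <- 0.25 + 0.02 * (0:8)

  # blend toward the across-gesture mean; separation = 1 leaves them as-is
  act_mean <- Reduce(`+`, acts) / length(acts)
  acts <- lapply(acts, function(a) act_mean + separation * (a - act_mean))
  freq_mean <- mean(freqs)
  freqs <- freq_mean + separation * (freqs - freq_mean)
  axis_mean <- Reduce(`+`, axes) / length(axes)
  axes <- lapply(axes, function(ax) {
    b <- axis_mean + separation * (ax - axis_mean)
    b / sqrt(rowSums(b^2))
  })

  tpl <- tibble(label = gesture_factor(codes),
                emg_activation = acts,
                motion_axis = axes,
                motion_freq = freqs,
                motion_amp = amps)
  d <- template_min_distance(tpl)
  if (d < min_cos_dist * separation^2) {
    abort(sprintf("template set degenerate: min pairwise cosine distance %.4g < %.4g",
                  d, min_cos_dist * separation^2),
          class = "handwashr_validation_error")
  }
  tpl
}

#' @rdname default_templates
#' @param templates A template tibble.
#' @return `template_min_distance()` returns the minimum pairwise cosine
#'   distance between flattened activation patterns.
#' @export
template_min_distance <- function(templates) {
  flat <- do.call(rbind, lapply(templates$emg_activation, as.vector))
  nrm <- flat / sqrt(rowSums(flat^2))
  sim <- tcrossprod(nrm)
  min(1 - sim[upper.tri(sim)])
}

#' Draw per-subject acquisition profiles
#'
#' Each subject gets multiplicative lognormal per-channel EMG gains (a
#' placeholder for unmodelled inter-subject variability such as skin
#' conductivity), an EMG noise floor, and one armband placement rotation
#' offset per repetition (0 for the first repetition, then re-drawn
#' uniformly within `placement_max_angle`, emulating re-seating of the
#' armband between repetitions).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject: `subject_id`, `channel_gain`
#'   (list of 2 x 8 matrices), `placement_angles` (list of length
#'   `n_repetitions` vectors), `noise_floor`.
#' @export
subject_profiles <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(config$n_subjects), function(i) {
      gains <- matrix(exp(rnorm(16, sd = config$gain_sdlog)), 2, 8)
      angles <- c(0, runif(max(0, config$n_repetitions - 1),
                           -config$placement_max_angle,
                           config$placement_max_angle))
      tibble(subject_id = sprintf("S%02d", i),
             channel_gain = list(gains),
             placement_angles = list(angles),
             noise_floor = config$noise_floor)
    })
  })
}

#' Rotate EMG channels by a fractional electrode offset
#'
#' Emulates the armband sitting rotated on the forearm: the 8 electrode
#' activations are circularly shifted by `angle / (2 pi / 8)` electrode
#' positions, with linear interpolation between adjacent electrodes for
#' fractional shifts.
#'
#' @param activation A 2 x 8 (arm x channel) activation matrix.
#' @param angle Rotation angle in radians.
#' @return The mixed 2 x 8 matrix.
#' @export
mix_channels <- function(activation, angle) {
  frac <- angle / (2 * pi / 8)
  k <- floor(frac)
  w <- frac - k
  idx1 <- ((0:7 + k) %% 8) + 1
  idx2 <- ((0:7 + k + 1) %% 8) + 1
  (1 - w) * activation[, idx1, drop = FALSE] + w * activation[, idx2, drop = FALSE]
}

bandlimited_noise <- function(n, n_channels) {
  # 4th-order Butterworth band-pass 20-95 Hz at the 200 Hz EMG rate: a
  # standard surrogate spectrum for surface EMG
  bf <- signal::butter(4, c(20, 95) / (EMG_RATE / 2), type = "pass")
  x <- matrix(rnorm(n * n_channels), n, n_channels)
  apply(x, 2, function(col) as.numeric(signal::filter(bf, col)))
}

standardize_segments <- function(x, seg_id) {
  for (s in unique(seg_id)) {
    i <- seg_id == s
    v <- x[i]
    x[i] <- (v - mean(v)) / sd(v)
  }
  x
}

rotate_about_axis <- function(v, axis, theta) {
  # Rodrigues formula, vectorized over theta; v and axis are 3-vectors
  ct <- cos(theta); st <- sin(theta)
  kxv <- c(axis[2] * v[3] - axis[3] * v[2],
           axis[3] * v[1] - axis[1] * v[3],
           axis[1] * v[2] - axis[2] * v[1])
  kdv <- sum(axis * v)
  t(outer(v, ct) + outer(kxv, st) + outer(axis * kdv, 1 - ct))
}

perp_unit <- function(u) {
  p <- c(u[2] * 1 - u[3] * 0, u[3] * 0 - u[1] * 1, u[1] * 0 - u[2] * 0)  # u x e3
  if (sum(p^2) < 1e-12) p <- c(1, 0, 0)
  p / sqrt(sum(p^2))
}

#' Simulate one session recording
#'
#' Synthesises the full nine-gesture routine in WHO order for one subject
#' and repetition. Per EMG channel the signal is subject gain x
#' placement-mixed template activation x a slow amplitude modulation
#' `(1 + 0.1 sin(2 pi f t))` x zero-mean unit-variance band-limited noise,
#' plus an additive noise floor, clipped and quantised to int8. The IMU
#' emits a small-angle sinusoidal rotation about the gesture's motion axis
#' as unit quaternions, gravity rotated into the sensor frame plus a
#' tangential sinusoid and noise on the accelerometer, and the analytic
#' angular rate plus noise on the gyroscope.
#'
#' @param templates Template tibble from [default_templates()].
#' @param profile One row of [subject_profiles()].
#' @param config A [sim_config()].
#' @param repetition Which repetition (indexes the profile's placement
#'   angle).
#' @param seed Integer seed for the noise draws.
#' @return A [session_recording()].
#' @export
simulate_session <- function(templates, profile, config, repetition = 1L,
                             seed = config$seed) {
  if (repetition > config$n_repetitions) {
    abort("repetition exceeds config$n_repetitions",
          class = "handwashr_validation_error")
  }
  n_seg_imu <- round(config$gesture_duration_s * IMU_RATE)
  n_seg_emg <- round(config$gesture_duration_s * EMG_RATE)
  n_imu <- 9L * n_seg_imu
  n_emg <- 9L * n_seg_emg
  seg_imu <- rep(1:9, each = n_seg_imu)
  seg_emg <- rep(1:9, each = n_seg_emg)
  gains <- profile$channel_gain[[1]]
  angle <- profile$placement_angles[[1]][repetition]
  nf <- profile$noise_floor

  # per-gesture amplitude profile for every arm x channel, EMG-rate time
  t_emg <- (seq_len(n_emg) - 1) / EMG_RATE
  amp <- array(0, dim = c(n_emg, 8, 2))
  for (g in 1:9) {
    mixed <- mix_channels(templates$emg_activation[[g]], angle)
    i <- seg_emg == g
    env <- 1 + 0.1 * sin(2 * pi * templates$motion_freq[g] * t_emg[i])
    for (arm in 1:2) {
      amp[i, , arm] <- outer(env, gains[arm, ] * mixed[arm, ])
    }
  }
  if (config$crossfade_s > 0) {
    ncf <- round(config$crossfade_s * EMG_RATE)
    for (g in 1:8) {
      b <- g * n_seg_emg
      lo <- max(1, b - ncf %/% 2); hi <- min(n_emg, b + ncf %/% 2)
      w <- seq(0, 1, length.out = hi - lo + 1)
      pre <- amp[lo, , , drop = FALSE]; post <- amp[hi, , , drop = FALSE]
      for (j in seq_along(w)) {
        amp[lo + j - 1, , ] <- (1 - w[j]) * pre[1, , ] + w[j] * post[1, , ]
      }
    }
  }

  withr::with_seed(seed, {
    streams <- lapply(1:2, function(arm) {
      carrier <- bandlimited_noise(n_emg, 8)
      floor_noise <- bandlimited_noise(n_emg, 8)
      emg <- matrix(0, n_emg, 8)
      for (ch in 1:8) {
        c_std <- standardize_segments(carrier[, ch], seg_emg)
        f_std <- standardize_segments(floor_noise[, ch], seg_emg)
        emg[, ch] <- amp[, ch, arm] * c_std + nf * f_std
      }
      emg <- pmin(pmax(round(emg), -128), 127)

      t_imu <- (seq_len(n_imu) - 1) / IMU_RATE
      imu <- matrix(0, n_imu, 10)
      for (g in 1:9) {
        i <- seg_imu == g
        u <- templates$motion_axis[[g]][arm, ]
        f <- templates$motion_freq[g]
        a <- templates$motion_amp[g]
        theta <- a * sin(2 * pi * f * t_imu[i])
        imu[i, 1] <- cos(theta / 2)
        imu[i, 2:4] <- outer(sin(theta / 2), u)
        grav <- rotate_about_axis(c(0, 0, 9.81), u, -theta)
        tang <- outer(0.5 * a * (2 * pi * f)^2 * sin(2 * pi * f * t_imu[i]),
                      perp_unit(u))
        imu[i, 5:7] <- grav + tang +
          matrix(rnorm(sum(i) * 3, sd = config$acc_noise_sd), ncol = 3)
        imu[i, 8:10] <- outer(a * 2 * pi * f * cos(2 * pi * f * t_imu[i]), u) +
          matrix(rnorm(sum(i) * 3, sd = config$gyro_noise_sd), ncol = 3)
      }
      armband_stream(emg, imu, t0 = 0)
    })
  })
  session_recording(streams[[1]], streams[[2]],
                    labels = gesture_codes()[seg_imu],
                    subject_id = profile$subject_id,
                    repetition = repetition)
}

#' Simulate and write a full cohort
#'
#' Draws one [subject_profiles()] row per subject (placement re-drawn per
#' repetition), simulates `n_subjects x n_repetitions` sessions, writes each
#' with [write_session()] under `out_dir/<subject>_r<rep>/`, and writes a
#' `manifest.json`. The whole cohort is a pure function of `config`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [dataset_manifest()].
#' @export
simulate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create cohort directory '%s'", out_dir),
          class = "handwashr_io_error")
  }
  templates <- default_templates(config$separation, seed = config$seed)
  profiles <- subject_profiles(config, seed = config$seed + 1L)
  session_seeds <- withr::with_seed(config$seed + 2L, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      config$n_subjects * config$n_repetitions),
           config$n_subjects, config$n_repetitions)
  })
  dirs <- character(0)
  for (i in seq_len(config$n_subjects)) {
    for (r in seq_len(config$n_repetitions)) {
      s <- simulate_session(templates, profiles[i, ], config, repetition = r,
                            seed = session_seeds[i, r])
      d <- sprintf("%s_r%d", profiles$subject_id[i], r)
      write_session(s, file.path(out_dir, d))
      dirs <- c(dirs, d)
    }
  }
  man <- dataset_manifest(dirs, profiles$subject_id, root = out_dir)
  write_manifest(man, out_dir)
  man
}
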
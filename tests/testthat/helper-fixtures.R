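# shared fixtures: all synthetic, generated in code at test time

# a zero-signal armband stream of the given duration (seconds)
make_zero_stream <- function(dur_s) {
  n_emg <- dur_s * 200
  n_imu <- dur_s * 50
  imu <- matrix(0, n_imu, 10)
  imu[, 1] <- 1              # identity quaternion
  imu[, 7] <- 9.81           # gravity on z
  armband_stream(matrix(0L, n_emg, 8), imu, t0 = 0)
}

# a structurally valid session with constant labels per 'dur_s' block
make_zero_session <- function(gestures = "G1", dur_s = 5,
                              subject_id = "T01", repetition = 1) {
  total <- dur_s * length(gestures)
  session_recording(make_zero_stream(total), make_zero_stream(total),
                    labels = rep(gestures, each = dur_s * 50),
                    subject_id = subject_id, repetition = repetition)
}

# a small simulated routine session (all 9 gestures)
make_sim_session <- function(dur_s = 1, seed = 11, separation = 1,
                             noise_floor = 1) {
  cfg <- sim_config(n_subjects = 1, n_repetitions = 1,
                    gesture_duration_s = dur_s, seed = seed,
                    separation = separation, noise_floor = noise_floor)
  tpl <- default_templates(separation, seed = seed)
  prof <- subject_profiles(cfg, seed = seed + 1)
  simulate_session(tpl, prof[1, ], cfg, repetition = 1, seed = seed + 2)
}

# a small cohort written to a temp dir; returns the manifest
make_sim_cohort <- function(n_subjects = 3, n_repetitions = 1, dur_s = 2.5,
                            seed = 21, separation = 1,
                            dir = withr::local_tempdir(.local_envir = parent.frame())) {
  simulate_cohort(sim_config(n_subjects = n_subjects,
                             n_repetitions = n_repetitions,
                             gesture_duration_s = dur_s, seed = seed,
                             separation = separation), dir)
}

# independent brute-force Viterbi oracle: enumerate all 9^T state paths
enumerate_map_path <- function(obs, hmm) {
  obs <- as.integer(gesture_factor(obs))
  Tn <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:9), Tn))[, Tn:1, drop = FALSE])
  lpar <- hmm_log_params(hmm)
  logA <- lpar$logA; logB <- lpar$logB; logpi <- lpar$logpi
  lp <- logpi[paths[, 1]] + logB[cbind(paths[, 1], obs[1])]
  if (Tn > 1) {
    for (t in 2:Tn) {
      lp <- lp + logA[cbind(paths[, t - 1], paths[, t])] +
        logB[cbind(paths[, t], obs[t])]
    }
  }
  # ties toward lexicographically smallest path (paths are enumerated with
  # the first state varying slowest), matching the decoder's tie-break
  best <- which(lp == max(lp))
  gesture_codes()[paths[best[1], ]]
}

# count label switches in a sequence
n_switches <- function(x) sum(diff(as.integer(gesture_factor(x))) != 0)
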
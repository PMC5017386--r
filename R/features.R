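#' Feature extraction configuration
#'
#' @param wavelet_level Decomposition depth `L` (>= 0). Each channel
#'   contributes `L + 1` wavelet features (one per detail level plus the
#'   final approximation), so the per-frame feature dimension is
#'   `36 + 36 * (L + 1)`.
#' @param wavelet_order Daubechies family index (default 4, i.e. db4;
#'   supported 1-10).
#' @param emg_window Centered EMG window length in 200 Hz samples (default
#'   128, i.e. 0.64 s of context).
#' @param imu_window Centered IMU window length in 50 Hz samples (default
#'   32).
#' @param energy_epsilon Floor added inside the log of the level energies;
#'   also the fill value (as `log10(energy_epsilon)`) for decomposition
#'   levels beyond the dyadic feasibility of the window.
#' @return A `feature_config` object.
#' @export
feature_config <- function(wavelet_level = 10L, wavelet_order = 4L,
                           emg_window = 128L, imu_window = 32L,
                           energy_epsilon = 1e-12) {
  if (wavelet_level < 0) abort("wavelet_level must be >= 0",
                               class = "handwashr_validation_error")
  if (emg_window < 2 || imu_window < 2) {
    abort("windows must be >= 2 samples", class = "handwashr_validation_error")
  }
  if (energy_epsilon <= 0) abort("energy_epsilon must be > 0",
                                 class = "handwashr_validation_error")
  structure(list(wavelet_level = as.integer(wavelet_level),
                 wavelet_order = as.integer(wavelet_order),
                 emg_window = as.integer(emg_window),
                 imu_window = as.integer(imu_window),
                 energy_epsilon = energy_epsilon),
            class = "feature_config")
}

#' @rdname feature_config
#' @param cfg A `feature_config`.
#' @return `feature_dim()` returns the per-frame feature dimension
#'   `36 + 36 * (L + 1)`.
#' @export
feature_dim <- function(cfg) {
  36L + 36L * (cfg$wavelet_level + 1L)
}

#' Wavelet level energies and log-energy features of one window
#'
#' Performs a periodized orthonormal multi-level Daubechies decomposition of
#' `window` down to `min(L, max feasible level)`; the transform preserves
#' total energy (Parseval), so the per-level mean-square coefficient
#' energies partition the window's energy. `wavelet_level_energies()`
#' returns those raw mean squares (detail levels 1..L, `NA` where a level is
#' beyond the dyadic feasibility of the window, then the final
#' approximation). `wavelet_level_features()` returns the feature used
#' downstream, `log10(eps + energy)`, with infeasible levels filled with
#' `log10(eps)`.
#'
#' @param window Numeric vector, length >= 2 (odd lengths are padded by
#'   repeating the last sample).
#' @param L Decomposition depth (>= 0).
#' @param order Daubechies family index (1-10).
#' @param eps Energy floor.
#' @return A numeric vector of length `L + 1`.
#' @examples
#' w <- sin(1:128)
#' # energies partition the signal energy (orthonormal transform)
#' e <- wavelet_level_energies(w, L = 5)
#' counts <- c(2^-(1:5) * 128, 4)
#' all.equal(sum(e * counts), sum(w^2))
#' @export
wavelet_level_energies <- function(window, L, order = 4L) {
  if (length(window) < 2) abort("window must have at least 2 samples",
                                class = "handwashr_validation_error")
  cpp_level_energies(as.numeric(window), as.integer(L), as.integer(order))
}

#' @rdname wavelet_level_energies
#' @export
wavelet_level_features <- function(window, L, order = 4L, eps = 1e-12) {
  e <- wavelet_level_energies(window, L, order)
  ifelse(is.na(e), log10(eps), log10(eps + e))
}

feature_names <- function(L) {
  arms <- c("l", "r")
  lev <- c(paste0("d", seq_len(L)), "a")[seq_len(L + 1)]
  if (L == 0) lev <- "a"
  emg_ch <- as.vector(t(outer(arms, 1:8, paste0)))          # l1..l8, r1..r8
  imu_ch <- as.vector(t(outer(arms, IMU_CHANNELS,
                              function(a, c) paste(a, c, sep = "_"))))
  c(paste0("emg_", emg_ch, "_raw"),
    as.vector(t(outer(paste0("emg_", emg_ch), lev, paste, sep = "_"))),
    paste0("imu_", imu_ch, "_raw"),
    as.vector(t(outer(paste0("imu_", imu_ch), lev, paste, sep = "_"))))
}

#' Extract per-frame features from a session
#'
#' Builds one feature vector per IMU frame (50 Hz). For frame `i`, the EMG
#' sample at index `4 i` (the 200/50 rate ratio) anchors a centered,
#' reflection-padded `emg_window`-sample window per EMG channel, yielding 16
#' raw (center-sample) values and 16 blocks of `L + 1` wavelet log-energy
#' features; a centered `imu_window`-sample window per IMU channel yields 20
#' raw values and 20 wavelet blocks. EMG features are therefore computed at
#' full 200 Hz resolution and downsampled at the feature level by taking
#' every 4th frame position, preserving high-frequency content. Column
#' order: 16 raw EMG, 16 (L+1) EMG wavelet, 20 raw IMU, 20 (L+1) IMU
#' wavelet, giving `36 + 36 (L + 1)` feature columns (432 at L = 10).
#'
#' @param session A [session_recording()].
#' @param cfg A [feature_config()].
#' @return A tibble with identification columns `subject_id`, `repetition`,
#'   `frame` (0-based), `label`, followed by the feature columns. The block
#'   layout is attached as attribute `"layout"`, the configuration as
#'   `"feature_config"`.
#' @export
extract_features <- function(session, cfg = feature_config()) {
  stopifnot(inherits(session, "session_recording"))
  nf <- n_frames(session)
  min_s <- max(cfg$emg_window / EMG_RATE, cfg$imu_window / IMU_RATE)
  if (nf / IMU_RATE < min_s) {
    abort(sprintf("session too short for feature windows: need at least %.2f s",
                  min_s),
          class = "handwashr_validation_error")
  }
  L <- cfg$wavelet_level
  centers_emg <- (seq_len(nf) - 1L) * 4L
  centers_imu <- seq_len(nf) - 1L

  emg_sig <- cbind(session$left$emg, session$right$emg)      # 16 channels
  imu_sig <- cbind(session$left$imu, session$right$imu)      # 20 channels

  raw_emg <- vapply(seq_len(16),
                    function(ch) cpp_center_values(emg_sig[, ch], centers_emg),
                    numeric(nf))
  wav_emg <- lapply(seq_len(16), function(ch) {
    cpp_window_features(emg_sig[, ch], centers_emg, cfg$emg_window, L,
                        cfg$wavelet_order, cfg$energy_epsilon)
  })
  raw_imu <- vapply(seq_len(20),
                    function(ch) cpp_center_values(imu_sig[, ch], centers_imu),
                    numeric(nf))
  wav_imu <- lapply(seq_len(20), function(ch) {
    cpp_window_features(imu_sig[, ch], centers_imu, cfg$imu_window, L,
                        cfg$wavelet_order, cfg$energy_epsilon)
  })

  X <- cbind(raw_emg, do.call(cbind, wav_emg), raw_imu, do.call(cbind, wav_imu))
  colnames(X) <- feature_names(L)
  stopifnot(ncol(X) == feature_dim(cfg), all(is.finite(X)))

  out <- tibble(subject_id = session$subject_id,
                repetition = session$repetition,
                frame = centers_imu,
                label = session$labels)
  out <- dplyr::bind_cols(out, as_tibble(X))
  attr(out, "layout") <- list(emg_raw = 16L, emg_wavelet = 16L * (L + 1L),
                              imu_raw = 20L, imu_wavelet = 20L * (L + 1L))
  attr(out, "feature_config") <- cfg
  out
}

#' @rdname extract_features
#' @param features A feature tibble from `extract_features()`.
#' @return `feature_matrix()` returns the numeric feature columns as a
#'   matrix (dropping the identification columns).
#' @export
feature_matrix <- function(features) {
  id_cols <- intersect(c("subject_id", "repetition", "frame", "label"),
                       names(features))
  as.matrix(features[, setdiff(names(features), id_cols)])
}
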
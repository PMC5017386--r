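#' Subject-wise k-fold split
#'
#' Shuffles the subjects with the given seed and cuts them into `k`
#' contiguous folds whose sizes differ by at most one (17 subjects in 5
#' folds gives sizes 4, 4, 3, 3, 3). All sessions of a subject land in the
#' same fold, so evaluation is always on unseen subjects.
#'
#' @param subjects Character vector of subject ids.
#' @param k Number of folds (<= number of subjects).
#' @param seed Integer seed for the shuffle.
#' @return A tibble with columns `subject_id` and `fold` (1..k), attribute
#'   `"seed"`.
#' @export
subject_kfold <- function(subjects, k, seed = 1L) {
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of subjects (%d)", k, n),
          class = "handwashr_validation_error")
  }
  shuffled <- withr::with_seed(seed, sample(subjects))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split <- tibble(subject_id = shuffled,
                  fold = rep(seq_len(k), times = sizes))
  attr(split, "seed") <- seed
  split[order(match(split$subject_id, subjects)), ]
}

confusion_counts <- function(truth, pred) {
  table(factor(truth, levels = gesture_codes()),
        factor(pred, levels = gesture_codes()))
}

#' Cross-validated evaluation of the full recognition chain
#'
#' For each fold: features of the training subjects are (optionally strided
#' and) used to fit the standardizer and the one-vs-all ensemble — test-fold
#' frames never touch either — then every test session is predicted frame by
#' frame and its label sequence decoded with the chain HMM (each session is
#' one routine instance). Recognition rate is frame-level accuracy over all
#' test frames.
#'
#' @param manifest A [dataset_manifest()] (e.g. from [simulate_cohort()]).
#' @param feat_cfg A [feature_config()].
#' @param train_cfg A [train_config()].
#' @param hmm A [build_who_chain()] model.
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param train_stride Keep every `train_stride`-th frame of each training
#'   session when fitting (default 1 = all frames). Adjacent 50 Hz frames
#'   are highly redundant, so moderate strides cut training cost with little
#'   effect on the fit; evaluation always uses every test frame.
#' @param predict_fun Optional override of the classifier for
#'   oracle/baseline studies: `function(train_features, test_features)`
#'   returning per-frame labels for the test features. When supplied, the
#'   ensemble is not trained.
#' @return A `cv_report` object; see [tidy.cv_report()] and
#'   [glance.cv_report()].
#' @export
run_cv <- function(manifest, feat_cfg = feature_config(),
                   train_cfg = train_config(), hmm = build_who_chain(),
                   k = 5L, seed = 1L, train_stride = 1L,
                   predict_fun = NULL) {
  paths <- manifest_sessions(manifest)
  sessions <- lapply(paths, read_session)
  feats <- lapply(sessions, extract_features, cfg = feat_cfg)
  subj <- vapply(sessions, function(s) s$subject_id, character(1))
  rm(sessions)
  split <- subject_kfold(manifest$subjects, k, seed)
  fold_of <- setNames(split$fold, split$subject_id)

  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train_idx <- which(fold_of[subj] != f)
    test_idx <- which(fold_of[subj] == f)
    train_tbl <- dplyr::bind_rows(lapply(feats[train_idx], function(x) {
      x[seq(1, nrow(x), by = train_stride), ]
    }))
    if (is.null(predict_fun)) {
      ens <- train_ensemble(train_tbl, train_cfg)
      predict_labels <- function(test_tbl) predict_frames(ens, test_tbl)$.pred
    } else {
      predict_labels <- function(test_tbl) {
        gesture_factor(predict_fun(train_tbl, test_tbl))
      }
    }
    conf_ann <- matrix(0L, 9, 9, dimnames = list(gesture_codes(), gesture_codes()))
    conf_hmm <- conf_ann
    for (i in test_idx) {
      truth <- gesture_factor(feats[[i]]$label)
      ann_lab <- predict_labels(feats[[i]])
      hmm_lab <- viterbi_decode(ann_lab, hmm)
      conf_ann <- conf_ann + unclass(confusion_counts(truth, ann_lab))
      conf_hmm <- conf_hmm + unclass(confusion_counts(truth, hmm_lab))
    }
    per_fold[[f]] <- list(fold = f,
                          confusion_ann = conf_ann, confusion_hmm = conf_hmm,
                          rate_ann = sum(diag(conf_ann)) / sum(conf_ann),
                          rate_hmm = sum(diag(conf_hmm)) / sum(conf_hmm),
                          n_frames = sum(conf_ann))
  }
  structure(list(per_fold = per_fold, k = k, seed = seed,
                 feat_cfg = feat_cfg, train_cfg = train_cfg, hmm = hmm),
            class = "cv_report")
}

#' Tidy and summarize a cross-validation report
#'
#' @param x A `cv_report` from [run_cv()].
#' @param ... Unused.
#' @return `tidy()` gives one row per fold (`fold`, `n_frames`, `rate_ann`,
#'   `rate_hmm`); `glance()` one row with mean and sample (n-1) standard
#'   deviation of both rates across folds.
#' @export
tidy.cv_report <- function(x, ...) {
  purrr::map_dfr(x$per_fold, function(pf) {
    tibble(fold = pf$fold, n_frames = pf$n_frames,
           rate_ann = pf$rate_ann, rate_hmm = pf$rate_hmm)
  })
}

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  td <- tidy(x)
  tibble(k = x$k,
         n_frames = sum(td$n_frames),
         mean_rate_ann = mean(td$rate_ann),
         sd_rate_ann = sd(td$rate_ann),
         mean_rate_hmm = mean(td$rate_hmm),
         sd_rate_hmm = sd(td$rate_hmm))
}

#' @export
print.cv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_report> %d-fold subject CV on %d frames\n", g$k, g$n_frames))
  cat(sprintf("  ANN rate: %.2f%% (+/- %.2f%%)\n",
              100 * g$mean_rate_ann, 100 * g$sd_rate_ann))
  cat(sprintf("  HMM rate: %.2f%% (+/- %.2f%%)\n",
              100 * g$mean_rate_hmm, 100 * g$sd_rate_hmm))
  invisible(x)
}

#' @rdname tidy.cv_report
#' @param report A `cv_report`.
#' @param stage `"ann"` or `"hmm"`.
#' @return `confusion_matrix()` returns the 9 x 9 confusion count matrix
#'   summed over folds (rows = truth, columns = prediction).
#' @export
confusion_matrix <- function(report, stage = c("ann", "hmm")) {
  stage <- match.arg(stage)
  key <- paste0("confusion_", stage)
  Reduce(`+`, lapply(report$per_fold, `[[`, key))
}

#' Hyperparameter sweep over one axis
#'
#' Re-runs [run_cv()] varying a single hyperparameter (hidden `nodes`,
#' hidden `layers`, or `wavelet_level`) while holding everything else at the
#' supplied base configurations, mirroring the incremental optimization such
#' pipelines are tuned by.
#'
#' @param manifest A [dataset_manifest()].
#' @param axis One of `"nodes"`, `"layers"`, `"wavelet_level"`.
#' @param values Values to sweep.
#' @param feat_cfg,train_cfg,hmm,k,seed,train_stride Passed to [run_cv()].
#' @return A `sweep_result` tibble: `axis`, `value`, `feature_dim`,
#'   `mean_rate_ann`, `sd_rate_ann`, `mean_rate_hmm`, `sd_rate_hmm`.
#' @export
run_sweep <- function(manifest, axis = c("nodes", "layers", "wavelet_level"),
                      values, feat_cfg = feature_config(),
                      train_cfg = train_config(), hmm = build_who_chain(),
                      k = 5L, seed = 1L, train_stride = 1L) {
  axis <- match.arg(axis)
  if (length(values) == 0) {
    abort("values must be non-empty", class = "handwashr_validation_error")
  }
  rows <- lapply(values, function(v) {
    fc <- feat_cfg
    tc <- train_cfg
    if (axis == "nodes") tc$hidden_nodes <- as.integer(v)
    if (axis == "layers") tc$hidden_layers <- as.integer(v)
    if (axis == "wavelet_level") fc$wavelet_level <- as.integer(v)
    rep <- run_cv(manifest, fc, tc, hmm, k = k, seed = seed,
                  train_stride = train_stride)
    g <- glance(rep)
    tibble(axis = axis, value = v, feature_dim = feature_dim(fc),
           mean_rate_ann = g$mean_rate_ann, sd_rate_ann = g$sd_rate_ann,
           mean_rate_hmm = g$mean_rate_hmm, sd_rate_hmm = g$sd_rate_hmm)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}
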
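test_that("subject folds partition the subjects with balanced sizes", {
  subjects <- sprintf("S%02d", 1:17)
  split <- subject_kfold(subjects, k = 5, seed = 1)
  expect_setequal(split$subject_id, subjects)
  expect_equal(sort(as.integer(table(split$fold))), c(3, 3, 3, 4, 4))
  # deterministic
  expect_identical(split, subject_kfold(subjects, k = 5, seed = 1))
  expect_false(identical(split$fold, subject_kfold(subjects, 5, seed = 2)$fold))
  # leave-one-subject-out
  loso <- subject_kfold(subjects, k = 17, seed = 1)
  expect_equal(as.integer(table(loso$fold)), rep(1, 17))
  expect_error(subject_kfold(subjects, k = 18), class = "handwashr_validation_error")
})

test_that("an oracle predictor yields perfect rates and diagonal confusions", {
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 1, dur_s = 1.5,
                         seed = 61)
  rep <- run_cv(man, feature_config(wavelet_level = 1), train_config(),
                build_who_chain(), k = 2, seed = 1,
                predict_fun = function(train, test) test$label)
  td <- tidy(rep)
  expect_equal(td$rate_ann, c(1, 1))
  expect_equal(td$rate_hmm, c(1, 1))
  cm <- confusion_matrix(rep, "ann")
  expect_equal(sum(diag(cm)), sum(cm))
  # conservation: all test frames are accounted for, in both matrices
  n_total <- 2 * 9 * 1.5 * 50
  expect_equal(sum(cm), n_total)
  expect_equal(unname(rowSums(confusion_matrix(rep, "ann"))),
               unname(rowSums(confusion_matrix(rep, "hmm"))))
})

test_that("cross-validation is reproducible and HMM smoothing does not hurt", {
  man <- make_sim_cohort(n_subjects = 3, n_repetitions = 1, dur_s = 2.5,
                         seed = 67)
  args <- list(man, feature_config(wavelet_level = 2),
               train_config(hidden_nodes = 10, max_iter = 25, seed = 1),
               build_who_chain(), k = 3, seed = 1, train_stride = 5)
  r1 <- do.call(run_cv, args)
  r2 <- do.call(run_cv, args)
  expect_equal(tidy(r1), tidy(r2))
  expect_identical(confusion_matrix(r1, "hmm"), confusion_matrix(r2, "hmm"))
  td <- tidy(r1)
  expect_true(all(td$rate_hmm >= td$rate_ann))
  expect_gt(glance(r1)$mean_rate_ann, 0.8)
})

test_that("training data never leaks into the test fold", {
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 2, dur_s = 1.5,
                         seed = 71)
  seen <- list()
  rep <- run_cv(man, feature_config(wavelet_level = 1), train_config(),
                build_who_chain(), k = 2, seed = 1,
                predict_fun = function(train, test) {
                  seen[[length(seen) + 1]] <<- list(
                    train = unique(train$subject_id),
                    test = unique(test$subject_id))
                  test$label
                })
  for (s in seen) {
    expect_length(intersect(s$train, s$test), 0)
  }
  # both subjects were tested exactly once per session
  expect_equal(sum(tidy(rep)$n_frames), 2 * 2 * 9 * 1.5 * 50)
})

test_that("a single-value sweep equals a direct cross-validation run", {
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 1, dur_s = 1.5,
                         seed = 73)
  fc <- feature_config(wavelet_level = 1)
  tc <- train_config(hidden_nodes = 5, max_iter = 10, seed = 1)
  sw <- run_sweep(man, "nodes", values = 5, fc, tc, build_who_chain(),
                  k = 2, seed = 1, train_stride = 10)
  direct <- glance(run_cv(man, fc, tc, build_who_chain(), k = 2, seed = 1,
                          train_stride = 10))
  expect_equal(sw$mean_rate_ann, direct$mean_rate_ann)
  expect_equal(sw$mean_rate_hmm, direct$mean_rate_hmm)
  expect_error(run_sweep(man, "nodes", numeric(0)),
               class = "handwashr_validation_error")
})

test_that("a wavelet-level sweep reports the measured feature dimensions", {
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 1, dur_s = 1.5,
                         seed = 79)
  sw <- run_sweep(man, "wavelet_level", values = c(0, 3, 10),
                  feature_config(), train_config(hidden_nodes = 5, max_iter = 5,
                                                 seed = 1),
                  build_who_chain(), k = 2, seed = 1, train_stride = 10)
  expect_equal(sw$feature_dim, c(72, 180, 432))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("frame accuracy rises with template separation", {
  rates <- sapply(c(0.2, 0.5, 1.0), function(sep) {
    mean(sapply(1:3, function(seed) {
      man <- make_sim_cohort(n_subjects = 4, n_repetitions = 1, dur_s = 2.5,
                             seed = 100 + seed, separation = sep)
      glance(run_cv(man, feature_config(wavelet_level = 3),
                    train_config(hidden_nodes = 10, max_iter = 25, seed = seed),
                    build_who_chain(), k = 2, seed = seed,
                    train_stride = 5))$mean_rate_ann
    }))
  })
  expect_true(all(diff(rates) >= 0))
})

test_that("confusion and smoothing plots build", {
  man <- make_sim_cohort(n_subjects = 2, n_repetitions = 1, dur_s = 1.5,
                         seed = 83)
  rep <- run_cv(man, feature_config(wavelet_level = 1), train_config(),
                build_who_chain(), k = 2, seed = 1,
                predict_fun = function(train, test) test$label)
  expect_s3_class(plot_confusion(rep, "hmm"), "ggplot")
  truth <- rep(gesture_codes(), each = 50)
  noisy <- truth
  noisy[seq(5, 440, by = 30)] <- "G1"
  expect_s3_class(plot_smoothing(truth, noisy, smooth_predictions(noisy)),
                  "ggplot")
})
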
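# a small two-cluster frame set relabeled as two gestures; separable by a
# wide margin, so a perfect training fit is expected
make_two_cluster <- function(n = 40, seed = 47) {
  withr::with_seed(seed, {
    tibble::tibble(
      label = gesture_factor(rep(c("G1", "G2L"), each = n / 2)),
      f1 = c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3)),
      f2 = c(rnorm(n / 2, 2, 0.3), rnorm(n / 2, -2, 0.3)))
  })
}

test_that("perfectly separated clusters are fit to 100% training accuracy", {
  feats <- make_two_cluster()
  ens <- train_ensemble(feats, train_config(hidden_nodes = 4, max_iter = 100,
                                            seed = 1))
  pred <- predict_frames(ens, feats)
  expect_identical(as.character(pred$.pred), as.character(feats$label))
  # margin-classifier oracle agrees: the clusters are split by f1 sign
  expect_identical(as.character(pred$.pred),
                   ifelse(feats$f1 < 0, "G1", "G2L"))
})

test_that("training is deterministic under a fixed seed and yields 9 networks", {
  feats <- make_two_cluster()
  cfg <- train_config(hidden_nodes = 3, max_iter = 30, seed = 5)
  e1 <- train_ensemble(feats, cfg)
  e2 <- train_ensemble(feats, cfg)
  expect_length(e1$networks, 9)
  expect_identical(names(e1$networks), gesture_codes())
  expect_identical(e1$networks$G1$theta, e2$networks$G1$theta)
  expect_identical(predict_frames(e1, feats), predict_frames(e2, feats))
})

test_that("scores are sigmoid responses in [0,1] and ties break to G1", {
  feats <- make_two_cluster()
  ens <- train_ensemble(feats, train_config(hidden_nodes = 3, max_iter = 20,
                                            seed = 2))
  pred <- predict_frames(ens, feats)
  scores <- as.matrix(pred[, paste0("score_", gesture_codes())])
  expect_true(all(scores >= 0 & scores <= 1))

  # zero all weights: every network answers 0.5, the tie goes to G1
  ens0 <- ens
  ens0$networks <- lapply(ens0$networks, function(net) {
    net$theta <- net$theta * 0
    net
  })
  pred0 <- predict_frames(ens0, feats)
  expect_true(all(pred0$.pred == "G1"))
})

test_that("prediction reuses the training standardizer without refitting", {
  feats <- make_two_cluster()
  ens <- train_ensemble(feats, train_config(hidden_nodes = 3, max_iter = 30,
                                            seed = 3))
  expect_equal(unname(ens$standardizer$mean),
               unname(colMeans(feature_matrix(feats))))
  # shifted test data must be standardized with the *training* statistics
  shifted <- feats
  shifted$f1 <- shifted$f1 + 100
  p_ref <- predict_frames(ens, feats)
  p_shift <- predict_frames(ens, shifted)
  expect_false(identical(p_ref$.pred, p_shift$.pred))  # no silent refit
})

test_that("zero-variance features are standardized with unit sd", {
  feats <- make_two_cluster()
  feats$f3 <- 7   # constant column
  ens <- train_ensemble(feats, train_config(hidden_nodes = 3, max_iter = 10,
                                            seed = 4))
  expect_equal(unname(ens$standardizer$sd[3]), 1)
})

test_that("single-class input is rejected", {
  feats <- make_two_cluster()
  feats$label <- gesture_factor(rep("G1", nrow(feats)))
  expect_error(train_ensemble(feats), "at least 2",
               class = "handwashr_validation_error")
})

test_that("feature dimension mismatches are rejected at prediction", {
  feats <- make_two_cluster()
  ens <- train_ensemble(feats, train_config(hidden_nodes = 3, max_iter = 10,
                                            seed = 6))
  expect_error(predict_frames(ens, feats[, c("label", "f1")]),
               class = "handwashr_validation_error")
})

test_that("a serialized ensemble predicts identically after reload", {
  feats <- make_two_cluster()
  ens <- train_ensemble(feats, train_config(hidden_nodes = 3, max_iter = 30,
                                            seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  ens2 <- read_ensemble(path)
  expect_equal(predict_frames(ens2, feats), predict_frames(ens, feats))
})
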
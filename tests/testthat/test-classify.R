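test_that("GNB separates well-separated Gaussians and matches the oracle", {
  set.seed(1)
  # disjoint class means, tiny pooled sd -> perfect test accuracy
  tr <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 3, 0.05), 20))
  lab <- rep(c("face", "scene"), each = 20)
  te <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 3, 0.05), 5))
  pred <- gnb_fit_predict(tr, lab, te)
  expect_equal(as.character(pred), rep(c("face", "scene"), each = 5))

  # 3-voxel random example: predictions equal direct density evaluation
  for (seed in 1:5) {
    set.seed(seed)
    tr <- matrix(rnorm(60), 20, 3)
    lab <- sample(rep(c("a", "b"), 10))
    te <- matrix(rnorm(30), 10, 3)
    expect_identical(as.character(gnb_fit_predict(tr, lab, te)),
                     oracle_gnb(tr, lab, te))
  }
})

test_that("exact GNB ties go to the lexicographically smaller label", {
  tr <- matrix(c(-1, -1.5, 1, 1.5), 4, 1)
  lab <- c("a", "a", "b", "b")
  te <- matrix(0, 1, 1) # equidistant from both means, equal priors
  expect_equal(as.character(gnb_fit_predict(tr, lab, te)), "a")
})

test_that("GNB guards degenerate training input", {
  tr <- matrix(rnorm(8), 4, 2)
  expect_error(gnb_fit_predict(tr, c("a", "a", "a", "a"), tr),
               class = "boldmvpa_invalid_argument")
  expect_error(gnb_fit_predict(tr, c("a", "a", "a", "b"), tr),
               class = "boldmvpa_invalid_argument")
  expect_warning(gnb_fit_predict(matrix(1, 4, 2), c("a", "a", "b", "b"),
                                 matrix(1, 2, 2)),
                 "floored")
})

test_that("logistic CV is perfect on separable patterns", {
  ps <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8, n_voxels = 2,
                        category_amp = 4, seed = 1)
  dec <- l2_logreg_cv_accuracy(ps, "category", lambda = 0.01)
  expect_equal(dec$mean_accuracy, 1.0)
  expect_equal(mean(dec$fold_accuracies$accuracy), dec$mean_accuracy)
})

test_that("label shuffling drives accuracy to chance levels", {
  accs <- vapply(1:5, function(seed) {
    ps <- toy_pattern_set(n_runs_per_cond = 5, trials_per_run = 20,
                          n_voxels = 10, category_amp = 0.5, seed = seed)
    # shuffle labels within run, independently of the patterns
    pm <- generate_label_permutations(ps$info$category, ps$info$run_id, 1,
                                      seed = seed + 100)
    ps$info$category <- pm$labels[, 1]
    l2_logreg_cv_accuracy(ps, "category")$mean_accuracy
  }, 1)
  expect_true(all(accs >= 0.35 & accs <= 0.65))
})

test_that("an overwhelming penalty removes the class information", {
  # weights shrink toward 0 as lambda grows; with no class structure in the
  # patterns the decision carries no information and accuracy sits at chance
  # on the balanced test pairs
  ps <- toy_pattern_set(n_runs_per_cond = 3, trials_per_run = 10,
                        n_voxels = 5, category_amp = 0, seed = 2)
  dec <- l2_logreg_cv_accuracy(ps, "category", lambda = 1e8)
  expect_gte(dec$mean_accuracy, 0.35)
  expect_lte(dec$mean_accuracy, 0.65)
})

test_that("single-class training folds are rejected", {
  ps <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8, seed = 3)
  ps$info$category <- rep("face", nrow(ps$X))
  expect_error(l2_logreg_cv_accuracy(ps, "category"),
               class = "boldmvpa_invalid_argument")
  # a 2-pair scheme where one held-out pair leaves a single-class training set
  ps3 <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8, seed = 4)
  ps3$info$category[ps3$info$run_id %in% c("run-01", "run-02")] <- "face"
  ps3$info$category[ps3$info$run_id %in% c("run-03", "run-04")] <- "scene"
  expect_error(l2_logreg_cv_accuracy(ps3, "category"),
               class = "boldmvpa_invalid_fold")
})

test_that("decoding results expose tidy and glance summaries", {
  ps <- toy_pattern_set(category_amp = 1, seed = 5)
  dec <- l2_logreg_cv_accuracy(ps, "category")
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("fold", "accuracy", "code"))
  gl <- glance(dec)
  expect_equal(gl$mean_accuracy, dec$mean_accuracy)
})
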
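test_that("permutations preserve per-run label counts and determinism", {
  ps <- toy_pattern_set(n_runs_per_cond = 5, trials_per_run = 20, seed = 1)
  labels <- ps$info$category
  runs <- ps$info$run_id
  pm <- generate_label_permutations(labels, runs, 200, seed = 3)
  expect_equal(dim(pm$labels), c(length(labels), 200))
  for (k in c(1, 57, 200)) {
    for (r in unique(runs)) {
      expect_equal(table(pm$labels[runs == r, k]),
                   table(labels[runs == r]))
    }
    expect_false(identical(pm$labels[, k], labels)) # identity excluded
  }
  pm2 <- generate_label_permutations(labels, runs, 200, seed = 3)
  expect_identical(pm$labels, pm2$labels)
})

test_that("a 2-trial run only yields its two arrangements", {
  labels <- c("a", "b")
  runs <- c("r1", "r1")
  pm <- generate_label_permutations(labels, runs, 50, seed = 1)
  for (k in seq_len(50)) {
    expect_true(identical(pm$labels[, k], c("b", "a")))
  }
  expect_warning(generate_label_permutations("a", "r1", 2, seed = 1),
                 "single trial")
  expect_error(generate_label_permutations(labels, runs, 0),
               class = "boldmvpa_invalid_argument")
})

test_that("empirical p follows the fraction-greater rule and its variant", {
  expect_equal(empirical_p(c(0.4, 0.5, 0.6, 0.7), 0.65), 0.25)
  expect_equal(empirical_p(c(0.4, 0.5), 0.9), 0) # above max(null)
  expect_equal(empirical_p(c(0.4, 0.5), 0.1), 1) # below min(null)
  expect_equal(empirical_p(c(0.4, 0.5, 0.6, 0.7), 0.65, "add_one"), 2 / 5)
  expect_error(empirical_p(numeric(0), 0.5),
               class = "boldmvpa_invalid_argument")
  # agreement with direct counting on random draws
  for (s in 1:5) {
    null <- with_seed_shuffle(seq(0, 1, length.out = 99), s)
    expect_equal(empirical_p(null, 0.37), oracle_empirical_p(null, 0.37))
  }
})

test_that("the group null of a single subject equals that subject's null", {
  pc <- simulate_pattern_cohort(n_subjects = 1, runs_per_condition = 3,
                                trials_per_run = 10, n_voxels = 5, seed = 2)
  ps <- pc$subjects[[1]]$control
  perm <- generate_label_permutations(ps$info$category, ps$info$run_id, 20,
                                      seed = 5, id = "g")
  nl <- roi_group_null(list(ps), list(perm))
  expect_equal(nl$group_null, as.numeric(nl$subject_null[1, ]))
})

test_that("misaligned permutation sets are rejected", {
  pc <- simulate_pattern_cohort(n_subjects = 2, runs_per_condition = 3,
                                trials_per_run = 10, n_voxels = 5, seed = 3)
  subs <- lapply(pc$subjects, function(s) s$control)
  p1 <- generate_label_permutations(subs[[1]]$info$category,
                                    subs[[1]]$info$run_id, 10, seed = 1,
                                    id = "x")
  p2 <- generate_label_permutations(subs[[2]]$info$category,
                                    subs[[2]]$info$run_id, 12, seed = 2,
                                    id = "x")
  expect_error(roi_group_null(subs, list(p1, p2)),
               class = "boldmvpa_alignment_error")
})

test_that("matched difference test is symmetric under identical conditions", {
  set.seed(7)
  null <- matrix(runif(3 * 400, 0.4, 0.6), 3)
  obs <- c(0.55, 0.5, 0.6)
  res <- tms_difference_test(null, null, obs, obs)
  expect_equal(res$observed, 0)
  # identical null matrices: all null differences are exactly 0, and the
  # strict ">" rule gives p = 0
  expect_equal(res$p, 0)
  # independent, identically distributed nulls: p hovers around 0.5
  null_b <- matrix(runif(3 * 400, 0.4, 0.6), 3)
  res_iid <- tms_difference_test(null, null_b, obs, obs)
  expect_gt(res_iid$p, 0.35)
  expect_lt(res_iid$p, 0.65)

  # single subject, nulls [0, 0.1], observed difference 0.2 -> p = 0
  res2 <- tms_difference_test(rbind(c(0.3, 0.4)), rbind(c(0.3, 0.3)),
                              0.5, 0.3)
  expect_equal(res2$observed, 0.2)
  expect_equal(res2$p, 0)
  expect_error(tms_difference_test(rbind(c(0.3, 0.4)), rbind(c(0.3, 0.3, 0.1)),
                                   0.5, 0.3),
               class = "boldmvpa_alignment_error")
})

test_that("perm-test objects expose tidy summaries and Bonferroni scaling", {
  tst <- above_chance_test(c(0.6, 0.7), seq(0.4, 0.6, length.out = 100),
                           n_tests = 4)
  expect_equal(tst$observed, 0.65)
  expect_equal(tst$p_bonferroni, min(1, tst$p * 4))
  td <- tidy(tst)
  expect_equal(td$n_perm, 100)
  expect_equal(td$n_tests, 4)
})
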
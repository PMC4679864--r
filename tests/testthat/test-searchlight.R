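test_that("searchlight map equals the per-center GNB oracle", {
  ps <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8,
                        category_amp = 0.5, seed = 1, dims = c(4, 4, 3),
                        region = cuboid_region(1:2, 1:2, 1:2))
  cv <- make_run_pair_folds(dplyr::distinct(ps$info, run_id, condition))
  map <- searchlight_accuracy_map(ps, "category", cv, cube_edge = 3)
  ora <- oracle_searchlight(ps, "category", 3, cv)
  expect_equal(map$valid, ora$valid)
  expect_equal(map$values[map$valid], ora$values[ora$valid],
               tolerance = 1e-10)
  expect_true(all(is.nan(map$values[!map$valid])))
  expect_true(all(map$values[map$valid] >= 0 & map$values[map$valid] <= 1))
})

test_that("an edge-1 searchlight equals single-voxel GNB", {
  ps <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8,
                        category_amp = 0.8, seed = 2, dims = c(3, 3, 2),
                        region = cuboid_region(1:3, 1:3, 1:2))
  cv <- make_run_pair_folds(dplyr::distinct(ps$info, run_id, condition))
  map <- searchlight_accuracy_map(ps, "category", cv, cube_edge = 1)
  fold <- boldmvpa:::trial_folds(ps, cv)
  for (v in seq_len(ncol(ps$X))) {
    accs <- vapply(1:2, function(f) {
      pred <- gnb_fit_predict(ps$X[fold != f, v, drop = FALSE],
                              ps$info$category[fold != f],
                              ps$X[fold == f, v, drop = FALSE])
      mean(pred == ps$info$category[fold == f])
    }, 1)
    cc <- ps$coords[v, ]
    expect_equal(map$values[cc[1], cc[2], cc[3]], mean(accs),
                 tolerance = 1e-10)
  }
})

test_that("occupancy rule marks border centers with small cubes invalid", {
  # 27-voxel cube on a 6x6x4 grid: corner centers have 2x2x2 clipped cubes
  ps <- toy_pattern_set(n_runs_per_cond = 2, trials_per_run = 8, seed = 3,
                        dims = c(6, 6, 4),
                        region = cuboid_region(1:6, 1:6, 1:4))
  map <- searchlight_accuracy_map(ps, "category", cube_edge = 3)
  expect_false(map$valid[1, 1, 1]) # 8 < 27/2
  expect_true(map$valid[3, 3, 2]) # full 27-voxel cube
  expect_true(map$valid[1, 3, 2]) # 18 >= 13.5
  expect_error(searchlight_accuracy_map(ps, "category", cube_edge = 2),
               class = "boldmvpa_invalid_argument")
})

test_that("searchlight accuracy is higher on a planted region than outside", {
  ps <- toy_pattern_set(n_runs_per_cond = 5, trials_per_run = 20,
                        category_amp = 0.1, seed = 4, dims = c(8, 8, 6),
                        region = cuboid_region(3:6, 3:6, 2:5))
  map <- searchlight_accuracy_map(ps, "category", cube_edge = 3)
  planted <- array(FALSE, dim = c(8, 8, 6))
  planted[cuboid_region(3:6, 3:6, 2:5)] <- TRUE
  inside <- mean(map$values[planted & map$valid])
  outside <- mean(map$values[!planted & map$valid &
                               !dilate_mask(planted, 2)])
  expect_gt(inside, outside)
  expect_gt(inside, 0.6)
})

test_that("accuracy maps are tidied and written as NIfTI with NaN padding", {
  ps <- toy_pattern_set(seed = 5, dims = c(4, 4, 3),
                        region = cuboid_region(1:2, 1:2, 1:2))
  map <- searchlight_accuracy_map(ps, "category", cube_edge = 3)
  td <- tidy(map)
  expect_equal(nrow(td), sum(map$valid))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_accuracy_map(map, f)
  back <- RNifti::readNifti(f)
  expect_equal(sum(is.nan(back)), sum(!map$valid))
})
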
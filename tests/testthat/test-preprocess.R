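make_test_run <- function(seed = 1, cfg = tiny_sim_config(seed = seed)) {
  ev <- make_run_design(cfg, "remember_faces", seed = seed)
  run <- simulate_run(cfg, ev, seed = seed + 1)
  list(vol = run$vol, events = ev, motion = run$motion, cfg = cfg)
}

test_that("design matrix has the documented columns and orthogonal baseline", {
  r <- make_test_run()
  n_t <- dim(r$vol$data)[4]
  X <- build_design_matrix(r$events, r$motion, n_t, r$vol$tr_s)
  # 2 stimulus (face + scene in one condition) + 6 motion + 6 polynomial
  expect_equal(ncol(X), 14)
  expect_equal(as.vector(table(attr(X, "roles")))[c(3, 2, 1)],
               c(2L, 6L, 6L), ignore_attr = TRUE)
  expect_equal(sum(attr(X, "roles") == "stimulus"), 2)
  poly_block <- X[, attr(X, "roles") == "baseline"]
  gram <- crossprod(poly_block)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  expect_false(any(colSums(abs(X)) == 0))
})

test_that("degenerate event tables raise an empty-design error", {
  r <- make_test_run()
  n_t <- dim(r$vol$data)[4]
  ev0 <- r$events[0, ]
  attr(ev0, "condition") <- "remember_faces"
  expect_error(build_design_matrix(ev0, r$motion, n_t, 1),
               class = "boldmvpa_empty_design")
  ev_zero <- r$events
  ev_zero$duration_s <- 0
  expect_error(build_design_matrix(ev_zero, r$motion, n_t, 1),
               class = "boldmvpa_empty_design")
})

test_that("baseline residualization removes nuisance and keeps stimulus", {
  r <- make_test_run(2)
  n_t <- dim(r$vol$data)[4]
  X <- build_design_matrix(r$events, r$motion, n_t, r$vol$tr_s)
  d <- dim(r$vol$data)[1:3]

  # series equal to 3 x motion column 1 -> all zeros
  vol <- r$vol
  vol$data <- array(rep(3 * X[, "x"], each = prod(d)), dim = c(d, n_t))
  out <- residualize_baseline(vol, X)
  expect_lt(max(abs(out$data)), 1e-8)

  # series equal to 2 x a stimulus column -> unchanged
  stim_col <- X[, which(attr(X, "roles") == "stimulus")[1]]
  vol$data <- array(rep(2 * stim_col, each = prod(d)), dim = c(d, n_t))
  out <- residualize_baseline(vol, X)
  expect_equal(out$data, vol$data, tolerance = 1e-8)

  # random series: residual orthogonal to every nuisance column
  out <- residualize_baseline(r$vol, X)
  Y <- boldmvpa:::as_time_by_voxel(out)
  nuis <- X[, attr(X, "roles") %in% c("motion", "baseline")]
  ndot <- crossprod(scale(nuis, scale = sqrt(colSums(nuis^2)), center = FALSE),
                    scale(Y, scale = sqrt(colSums(Y^2)), center = FALSE))
  expect_lt(max(abs(ndot)), 1e-6)
  expect_equal(dim(out$data), dim(r$vol$data))
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  r <- make_test_run(3)
  n_t <- dim(r$vol$data)[4]
  X <- build_design_matrix(r$events, r$motion, n_t, r$vol$tr_s)
  X2 <- cbind(X, dup = X[, 2])
  attr(X2, "roles") <- c(attr(X, "roles"), "motion")
  expect_error(residualize_baseline(r$vol, X2),
               class = "boldmvpa_rank_deficient")
})

test_that("z-scoring normalizes, is idempotent, and flags constant voxels", {
  r <- make_test_run(4)
  z <- zscore_run(r$vol)
  Y <- boldmvpa:::as_time_by_voxel(z)
  expect_lt(max(abs(colMeans(Y))), 1e-10)
  expect_lt(max(abs(apply(Y, 2, sd) - 1)), 1e-10)
  z2 <- zscore_run(z)
  expect_equal(z2$data, z$data, tolerance = 1e-10)

  vol <- r$vol
  vol$data[1, 1, 1, ] <- 5 # constant voxel
  zc <- zscore_run(vol)
  expect_true(all(zc$data[1, 1, 1, ] == 0))
  expect_equal(sum(attr(zc, "degenerate_voxels")), 1)
  expect_error(zscore_run(volume4d(array(1, c(2, 2, 2, 1)), 3.5, 1)),
               class = "boldmvpa_invalid_argument")
})

test_that("lag-window extraction picks the unique volume per trial", {
  cfg <- tiny_sim_config(seed = 5)
  ev <- make_run_design(cfg, "remember_faces", seed = 5)
  run <- simulate_run(cfg, ev, seed = 6)
  ps <- extract_trial_patterns(run$vol, ev, c(5, 6))
  expect_equal(nrow(ps$X), nrow(ev))
  # acquisition-start convention: onset 12 s, window (5,6), TR 1, t0 0
  # selects the volume acquired at t = 17 s
  t_sel <- run$vol$t0_s + (ps$info$volume - 1) * run$vol$tr_s
  expect_true(all(t_sel >= ev$onset_s + 5 & t_sel < ev$onset_s + 6))
  if (any(ev$onset_s == 12)) {
    expect_equal(t_sel[ev$onset_s == 12][1], 17)
  }
  # windows that cover no volume or several volumes are errors
  expect_error(extract_trial_patterns(run$vol, ev, c(5, 7.5)),
               class = "boldmvpa_ambiguous_window")
  expect_error(extract_trial_patterns(run$vol, ev, c(500, 501)),
               class = "boldmvpa_ambiguous_window")
  # masks restrict the voxel set
  ps_m <- extract_trial_patterns(run$vol, ev, c(5, 6), mask = cfg$regions$v)
  expect_equal(ncol(ps_m$X), nrow(cfg$regions$v))
})

test_that("noise-free planted runs recover the planted category pattern", {
  cfg <- sim_config(n_subjects = 1, grid_dims = c(6, 6, 4),
                    runs_per_condition = 2,
                    regions = list(v = cuboid_region(2:5, 2:5, 2:3)),
                    category_code = list(v = 0.5), relevance_code = list(),
                    disruption_factors = list(), noise_sd = 0,
                    drift_coeffs_range = c(0.05, 0.2), motion_coef_sd = 0,
                    subject_amp_scale_sd = 0, seed = 11)
  co <- simulate_cohort(cfg)
  pats <- extract_cohort_patterns(co, "category", mask = cfg$regions$v)
  ps <- pats[[1]]$control
  diff_pattern <- colMeans(ps$X[ps$info$category == "face", ]) -
    colMeans(ps$X[ps$info$category == "scene", ])
  planted <- cfg$category_code$v
  cosine <- sum(diff_pattern * planted) /
    sqrt(sum(diff_pattern^2) * sum(planted^2))
  expect_gt(cosine, 0.99)
})
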
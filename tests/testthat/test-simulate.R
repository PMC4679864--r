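test_that("null forward model yields a constant-zero volume", {
  cfg <- tiny_sim_config()
  cfg$category_code$v <- cfg$category_code$v * 0
  cfg$relevance_code$v <- cfg$relevance_code$v * 0
  cfg$noise_sd <- 0
  cfg$drift_coeffs_range <- c(0, 0)
  cfg$motion_coef_sd <- 0
  ev <- make_run_design(cfg, "remember_faces", seed = 2)
  run <- simulate_run(cfg, ev, seed = 3)
  expect_true(all(run$vol$data == 0))
})

test_that("a single planted voxel and trial reproduce the shifted HRF", {
  cfg <- sim_config(n_subjects = 1, grid_dims = c(2, 2, 2),
                    regions = list(v = cuboid_region(1, 1, 1)),
                    category_code = list(v = 0.7), relevance_code = list(),
                    disruption_factors = list(), noise_sd = 0,
                    drift_coeffs_range = c(0, 0), motion_coef_sd = 0,
                    seed = 1)
  ev <- tibble::tibble(onset_s = 4, duration_s = 1, category = "face",
                       match = "nonmatch", correct = TRUE)
  attr(ev, "condition") <- "remember_faces"
  attr(ev, "run_id") <- "run-01"
  attr(ev, "tms_condition") <- "control"
  attr(ev, "run_duration_s") <- 40
  run <- simulate_run(cfg, ev, seed = 2)
  series <- run$vol$data[1, 1, 1, ]
  # face sign +1, relevance sign +1 but no relevance code: expect
  # 0.7 * (HRF boxcar response) starting at onset 4 s
  h <- double_gamma_hrf(0.1, 32)
  drive <- as.numeric(seq(0, 39.9, by = 0.1) >= 4 &
                        seq(0, 39.9, by = 0.1) < 5)
  expected <- 0.7 * stats::convolve(drive, rev(h), type = "open")[
    seq(1, 400, by = 10)]
  expect_equal(series, expected, tolerance = 1e-10)
  # all other voxels silent
  expect_true(all(run$vol$data[2, , , ] == 0))
})

test_that("a zero disruption multiplier removes the relevance contribution", {
  cfg <- sim_config(n_subjects = 1, grid_dims = c(3, 3, 3),
                    regions = list(v = cuboid_region(1:2, 1:2, 1:2)),
                    category_code = list(), relevance_code = list(v = 0.5),
                    disruption_factors = list(v = 0), noise_sd = 0,
                    drift_coeffs_range = c(0, 0), motion_coef_sd = 0,
                    seed = 1)
  ev_c <- make_run_design(cfg, "remember_faces", seed = 4,
                          tms_condition = "control")
  ev_d <- make_run_design(cfg, "remember_faces", seed = 4,
                          tms_condition = "disrupted")
  run_c <- simulate_run(cfg, ev_c, seed = 5)
  run_d <- simulate_run(cfg, ev_d, seed = 5)
  expect_gt(max(abs(run_c$vol$data)), 0)
  expect_true(all(run_d$vol$data == 0))
})

test_that("cohort structure, determinism, and behavior model hold", {
  cfg <- tiny_sim_config(n_subjects = 2)
  co <- simulate_cohort(cfg)
  # 2 subjects x 2 sessions x (2 task conditions x 2 runs)
  expect_length(co$subjects, 2)
  expect_equal(sum(lengths(lapply(co$subjects, function(s)
    c(s$control, s$disrupted)))), 2 * 2 * 4)
  expect_equal(nrow(co$behavior), 4)
  expect_true(all(co$behavior$accuracy >= 0 & co$behavior$accuracy <= 1))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(simulate_cohort(cfg), d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
})

test_that("with zero behavior gain, accuracy is unrelated to code amplitude", {
  cfg <- sim_config(n_subjects = 40, runs_per_condition = 2,
                    trials_per_run = 4, matches_per_run = 1,
                    grid_dims = c(2, 2, 2),
                    regions = list(v = cuboid_region(1, 1, 1)),
                    category_code = list(), relevance_code = list(v = 0.1),
                    disruption_factors = list(v = 0.5),
                    behavior_model = list(baseline = 0.9, gain = 0,
                                          sd = 0.01, region = "v"),
                    seed = 3)
  # behavior draws happen before any volume simulation; avoid the expensive
  # part by asking only for the quantities the behavior model uses
  co <- simulate_cohort(cfg)
  ctrl <- co$behavior$accuracy[co$behavior$tms_condition == "control"]
  expect_lt(abs(cor(ctrl, co$amp_scales)), 0.4)
})

test_that("unknown region ids in codes are rejected", {
  expect_error(sim_config(regions = list(a = cuboid_region(1, 1, 1)),
                          category_code = list(b = 1),
                          relevance_code = list(),
                          disruption_factors = list()),
               class = "boldmvpa_unknown_region")
  expect_error(sim_config(regions = list(a = cuboid_region(1, 1, 1)),
                          category_code = list(),
                          relevance_code = list(),
                          disruption_factors = list(a = 1.5)),
               class = "boldmvpa_invalid_argument")
})

test_that("cohorts round-trip through the on-disk dataset layout", {
  cfg <- tiny_sim_config(seed = 9)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$behavior$accuracy, co$behavior$accuracy, tolerance = 1e-9)
  r0 <- co$subjects[[1]]$control[[1]]
  r1 <- back$subjects[["sub-01"]][["control"]][["run-01"]]
  expect_equal(r1$vol$data, r0$vol$data, tolerance = 1e-6)
  expect_equal(r1$vol$tr_s, r0$vol$tr_s)
  expect_equal(r1$events$onset_s, r0$events$onset_s)
  expect_equal(as.data.frame(r1$motion), as.data.frame(r0$motion),
               tolerance = 1e-6)
  expect_equal(attr(r1$events, "condition"), attr(r0$events, "condition"))
  # masks present: brain + one region
  expect_setequal(names(back$masks), c("brain", "v"))
  expect_equal(sum(back$masks$v), nrow(cfg$regions$v))
})
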
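make_null_inputs <- function(n_sub = 4, n_null = 10, d = c(6, 6, 4),
                             seed = 1, sd = 0.03, shift_fn = NULL) {
  boldmvpa:::with_seed(seed, {
    true_maps <- lapply(seq_len(n_sub), function(s) {
      m <- array(rnorm(prod(d), 0, sd), dim = d)
      if (!is.null(shift_fn)) m <- shift_fn(m)
      m
    })
    null_maps <- lapply(seq_len(n_sub), function(s) {
      lapply(seq_len(n_null), function(k) array(rnorm(prod(d), 0, sd), dim = d))
    })
    list(true_maps = true_maps, null_maps = null_maps)
  })
}

test_that("all-zero maps pass no voxel", {
  d <- c(5, 5, 3)
  zero <- array(0, dim = d)
  res <- suppressWarnings(searchlight_group_difference(
    list(zero, zero, zero), lapply(1:3, function(s) list(zero, zero, zero)),
    n_boot = 50, seed = 1))
  expect_equal(sum(res$binary_map), 0)
  expect_equal(nrow(res$clusters), 0)
})

test_that("bootstrap inference is bit-reproducible under a fixed seed", {
  inp <- make_null_inputs(seed = 4)
  r1 <- searchlight_group_difference(inp$true_maps, inp$null_maps,
                                     n_boot = 500, seed = 42)
  r2 <- searchlight_group_difference(inp$true_maps, inp$null_maps,
                                     n_boot = 500, seed = 42)
  expect_identical(r1$binary_map, r2$binary_map)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_identical(as.data.frame(r1$clusters), as.data.frame(r2$clusters))
})

test_that("a strong planted difference survives cluster correction", {
  d <- c(6, 6, 4)
  planted <- array(FALSE, dim = d)
  planted[cuboid_region(2:5, 2:5, 2:3)] <- TRUE
  shift <- function(m) { m[planted] <- m[planted] + 0.3; m }
  inp <- make_null_inputs(n_sub = 5, n_null = 20, d = d, seed = 5,
                          shift_fn = shift)
  res <- searchlight_group_difference(inp$true_maps, inp$null_maps,
                                      n_boot = 2000, seed = 6)
  expect_gt(sum(res$clusters$survives), 0)
  det <- surviving_mask(res)
  expect_gt(dice_coef(det, planted), 0.8)
})

test_that("misaligned inputs and unstable settings are flagged", {
  inp <- make_null_inputs(seed = 7)
  bad_null <- inp$null_maps
  bad_null[[2]] <- bad_null[[2]][1:5]
  expect_error(searchlight_group_difference(inp$true_maps, bad_null,
                                            n_boot = 200, seed = 1),
               class = "boldmvpa_alignment_error")
  bad_grid <- inp$true_maps
  bad_grid[[1]] <- array(0, dim = c(3, 3, 3))
  expect_error(searchlight_group_difference(bad_grid, inp$null_maps,
                                            n_boot = 200, seed = 1),
               class = "boldmvpa_shape_error")
  expect_warning(searchlight_group_difference(inp$true_maps, inp$null_maps,
                                              n_boot = 50, seed = 1),
                 "unstable")
})

test_that("voxel thresholds agree with direct quantile computation", {
  inp <- make_null_inputs(n_sub = 3, n_null = 6, d = c(3, 3, 2), seed = 9)
  n_boot <- 400
  res <- searchlight_group_difference(inp$true_maps, inp$null_maps,
                                      n_boot = n_boot, voxel_alpha = 0.05,
                                      seed = 11)
  # reproduce the bootstrap draws and the empirical quantile by hand
  n_null <- 6
  draw <- boldmvpa:::with_seed(11, matrix(sample.int(n_null, n_boot * 3,
                                                     replace = TRUE),
                                          n_boot, 3))
  v <- c(2, 2, 1)
  vals <- vapply(seq_len(n_boot), function(b) {
    mean(vapply(1:3, function(s) inp$null_maps[[s]][[draw[b, s]]][v[1], v[2], v[3]],
                1))
  }, 1)
  expect_equal(res$voxel_thresholds[v[1], v[2], v[3]],
               sort(vals)[ceiling(0.95 * n_boot)], tolerance = 1e-12)
})
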
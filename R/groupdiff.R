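#' Bootstrap group inference on searchlight difference maps
#'
#' Implements the nonparametric group analysis for condition differences in
#' searchlight accuracy: (1) the true group map is the across-subject mean
#' of the (smoothed) per-subject difference maps (control - disrupted); (2)
#' `n_boot` null group maps are built by drawing, for each subject, one of
#' that subject's `n_null` permutation-null difference maps uniformly with
#' replacement and averaging across subjects; (3) a voxel passes if its true
#' value strictly exceeds the voxel's empirical `1 - voxel_alpha` bootstrap
#' quantile; (4) passing voxels are grouped into face-connected clusters;
#' (5) every null group map is thresholded by the same per-voxel quantiles
#' and its maximum cluster size recorded; a true cluster survives if its
#' size strictly exceeds the `1 - cluster_alpha` quantile of the null
#' maximum sizes.
#'
#' @param true_maps List of per-subject difference maps (3D arrays or
#'   [accuracy_map()]s), already smoothed.
#' @param null_maps List (per subject) of lists of `n_null` difference maps
#'   under permuted labels, smoothed identically to the true maps.
#' @param n_boot Number of bootstrap group maps (warning below 100).
#' @param voxel_alpha Voxelwise level (default 0.005, i.e. the 99.5%
#'   bootstrap quantile).
#' @param cluster_alpha Cluster-extent level (default 0.005).
#' @param seed Seed for the bootstrap draws.
#' @param block_voxels,block_boots Chunk sizes bounding memory.
#' @return A `searchlight_group_test`: list with `binary_map` (logical 3D),
#'   `clusters` (a [extract_clusters()] report with `survives` filled),
#'   `group_map` (true mean difference), `voxel_thresholds` (3D array),
#'   `cluster_size_threshold`, `null_max_sizes`, `valid` mask.
#' @export
searchlight_group_difference <- function(true_maps, null_maps, n_boot = 1e5,
                                         voxel_alpha = 0.005,
                                         cluster_alpha = 0.005, seed = 1L,
                                         block_voxels = 512L,
                                         block_boots = 1024L) {
  if (n_boot < 100) {
    warn("n_boot < 100: bootstrap quantiles will be unstable.")
  }
  as_arr <- function(m) if (inherits(m, "accuracy_map")) m$values else m
  true_maps <- lapply(true_maps, as_arr)
  null_maps <- lapply(null_maps, function(s) lapply(s, as_arr))
  n_sub <- length(true_maps)
  n_null <- unique(vapply(null_maps, length, 1L))
  if (length(n_null) != 1) {
    abort("all subjects must have the same number of null maps.",
          class = "boldmvpa_alignment_error")
  }
  d <- dim(true_maps[[1]])
  all_dims <- c(lapply(true_maps, dim), lapply(null_maps, function(s) dim(s[[1]])))
  if (!all(vapply(all_dims, function(x) identical(x, d), TRUE))) {
    abort("maps do not share a common grid.", class = "boldmvpa_shape_error")
  }

  true_mat <- vapply(true_maps, as.numeric, numeric(prod(d))) # cells x subj
  nulls <- lapply(null_maps, function(s) vapply(s, as.numeric, numeric(prod(d))))
  valid_cells <- rowSums(is.finite(true_mat)) == n_sub
  for (s in seq_len(n_sub)) {
    valid_cells <- valid_cells & (rowSums(is.finite(nulls[[s]])) == n_null)
  }
  vix <- which(valid_cells)
  V <- length(vix)
  true_v <- rowMeans(true_mat[vix, , drop = FALSE])
  nulls_v <- lapply(nulls, function(m) m[vix, , drop = FALSE]) # V x n_null

  draw <- with_seed(seed, matrix(sample.int(n_null, n_boot * n_sub,
                                            replace = TRUE), n_boot, n_sub))

  # pass 1: per-voxel empirical 1 - voxel_alpha bootstrap quantile
  q_pos <- ceiling((1 - voxel_alpha) * n_boot)
  thr_v <- numeric(V)
  for (start in seq(1L, V, by = block_voxels)) {
    ix <- start:min(start + block_voxels - 1L, V)
    boot <- matrix(0, n_boot, length(ix))
    for (s in seq_len(n_sub)) {
      boot <- boot + t(nulls_v[[s]][ix, draw[, s], drop = FALSE])
    }
    boot <- boot / n_sub
    thr_v[ix] <- apply(boot, 2, function(col) sort(col)[q_pos])
  }
  pass_v <- true_v > thr_v

  binary <- array(FALSE, dim = d)
  binary[vix] <- pass_v
  clusters <- extract_clusters(binary)

  # pass 2: max null cluster size per bootstrap map under the same thresholds
  null_max <- integer(n_boot)
  for (start in seq(1L, n_boot, by = block_boots)) {
    bx <- start:min(start + block_boots - 1L, n_boot)
    boot <- matrix(0, V, length(bx))
    for (s in seq_len(n_sub)) {
      boot <- boot + nulls_v[[s]][, draw[bx, s], drop = FALSE]
    }
    boot <- boot / n_sub
    binmaps <- matrix(0L, prod(d), length(bx))
    binmaps[vix, ] <- (boot > thr_v) * 1L
    null_max[bx] <- cpp_max_cluster_sizes(binmaps, as.integer(d))
  }
  c_pos <- ceiling((1 - cluster_alpha) * n_boot)
  c_thr <- sort(null_max)[c_pos]
  clusters$survives <- clusters$size > c_thr

  group_map <- array(NaN, dim = d)
  group_map[vix] <- true_v
  thr_map <- array(NaN, dim = d)
  thr_map[vix] <- thr_v
  structure(list(binary_map = binary, clusters = clusters,
                 group_map = group_map, voxel_thresholds = thr_map,
                 cluster_size_threshold = c_thr, null_max_sizes = null_max,
                 valid = array(valid_cells, dim = d), n_boot = n_boot,
                 voxel_alpha = voxel_alpha, cluster_alpha = cluster_alpha,
                 seed = seed),
            class = "searchlight_group_test")
}

#' @export
print.searchlight_group_test <- function(x, ...) {
  cat(sprintf(paste0("<searchlight_group_test> %d voxels pass (alpha = %g); ",
                     "%d/%d clusters survive (size > %d)\n"),
              sum(x$binary_map), x$voxel_alpha, sum(x$clusters$survives),
              nrow(x$clusters), x$cluster_size_threshold))
  invisible(x)
}

#' @rdname searchlight_group_difference
#' @param x A `searchlight_group_test`.
#' @param ... Unused.
#' @method tidy searchlight_group_test
#' @export
tidy.searchlight_group_test <- function(x, ...) {
  as_tibble(as.data.frame(x$clusters))
}

#' @rdname searchlight_group_difference
#' @method glance searchlight_group_test
#' @export
glance.searchlight_group_test <- function(x, ...) {
  tibble(n_pass_voxels = sum(x$binary_map), n_clusters = nrow(x$clusters),
         n_surviving = sum(x$clusters$survives),
         cluster_size_threshold = x$cluster_size_threshold,
         n_boot = x$n_boot, voxel_alpha = x$voxel_alpha,
         cluster_alpha = x$cluster_alpha)
}
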
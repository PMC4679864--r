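# Shared fixture builders. Amplitudes are the frozen calibration values:
# 0.028 per voxel at the BOLD level gives ~70% single-subject searchlight
# decoding; 0.12 on a 27-voxel pattern-level ROI (0.15 on 12 voxels) gives
# ~70% logistic CV accuracy; 0.06 across a 6x6x5 region of a 12x12x8 grid
# is the searchlight difference-map operating point.

tiny_sim_config <- function(seed = 1L, n_subjects = 1, ...) {
  sim_config(n_subjects = n_subjects, grid_dims = c(6, 6, 4),
             runs_per_condition = 2,
             trials_per_run = 8, matches_per_run = 2,
             regions = list(v = cuboid_region(2:4, 2:4, 2:3)),
             category_code = list(v = 0.1), relevance_code = list(v = 0.1),
             disruption_factors = list(v = 0.5), seed = seed, ...)
}

# small pattern set with arbitrary geometry for classifier tests
toy_pattern_set <- function(n_runs_per_cond = 2, trials_per_run = 8,
                            n_voxels = 4, category_amp = 0, seed = 1L,
                            dims = NULL, region = NULL) {
  pc <- simulate_pattern_cohort(n_subjects = 1,
                                runs_per_condition = n_runs_per_cond,
                                trials_per_run = trials_per_run,
                                matches_per_run = 1, n_voxels = n_voxels,
                                category_amp = category_amp, seed = seed,
                                dims = dims, region = region)
  pc$subjects[[1]]$control
}

# per-subject observed accuracies + subject null matrices for one code and
# both sessions of a pattern-level cohort
roi_session_stats <- function(pc, code, n_perm, seed, lambda = 1) {
  out <- list()
  for (cond in c("control", "disrupted")) {
    subs <- lapply(pc$subjects, function(x) x[[cond]])
    perms <- lapply(seq_along(subs), function(s) {
      generate_label_permutations(subs[[s]]$info[[code]],
                                  subs[[s]]$info$run_id, n_perm,
                                  seed = seed + s, id = paste0(code, "-set"))
    })
    obs <- vapply(subs, function(ps) {
      l2_logreg_cv_accuracy(ps, code, lambda = lambda)$mean_accuracy
    }, 1)
    nl <- roi_group_null(subs, perms, lambda = lambda)
    out[[cond]] <- list(obs = obs, null = nl$subject_null,
                        group_null = nl$group_null)
  }
  out
}

# smoothed true + null difference maps for a pattern-level cohort (the input
# to searchlight_group_difference)
difference_maps <- function(pc, n_null, seed, cube_edge = 5, fwhm_mm = 8,
                            voxel_size_mm = 3.5, code = "relevance") {
  n_sub <- length(pc$subjects)
  lev2 <- if (code == "relevance") "relevant" else "scene"
  true_diff <- vector("list", n_sub)
  null_diff <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    maps <- lapply(c("control", "disrupted"), function(cond) {
      ps <- pc$subjects[[s]][[cond]]
      lab <- ps$info[[code]]
      pm <- generate_label_permutations(lab, ps$info$run_id, n_null,
                                        seed = seed + s * 2 +
                                          match(cond, c("control", "disrupted")),
                                        id = "sl")
      labmat <- cbind(as.integer(lab == lev2),
                      matrix(as.integer(pm$labels == lev2), nrow(pm$labels)))
      boldmvpa:::searchlight_batch(ps, labmat, cube_edge = cube_edge)
    })
    sm <- function(m) smooth_gaussian(m, fwhm_mm, voxel_size_mm)
    true_diff[[s]] <- sm(maps[[1]]$maps[[1]] - maps[[2]]$maps[[1]])
    null_diff[[s]] <- lapply(seq_len(n_null) + 1L, function(j) {
      sm(maps[[1]]$maps[[j]] - maps[[2]]$maps[[j]])
    })
  }
  list(true_diff = true_diff, null_diff = null_diff)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

with_seed_shuffle <- function(x, seed) boldmvpa:::with_seed(seed, sample(x))

surviving_mask <- function(test) {
  lab <- attr(test$clusters, "labels")
  keep <- test$clusters$cluster[test$clusters$survives]
  array(lab %in% keep, dim = dim(lab))
}
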
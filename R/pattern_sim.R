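#' Simulate trial patterns directly at the pattern level
#'
#' Generates the trial-by-voxel patterns that the preprocessing chain would
#' deliver, without simulating BOLD time series: each trial's pattern is
#' i.i.d. Gaussian noise plus the planted category pattern times the trial's
#' category sign plus the planted relevance pattern times the relevance sign
#' (times `attenuation` in the disrupted session). Run structure, label
#' balance and pseudo-randomization follow [make_run_design()]. This is the
#' fast substrate for permutation/bootstrap calibration studies; the full
#' BOLD forward model lives in [simulate_run()].
#'
#' Per-voxel planted patterns are `amplitude * (+/-1)` with fixed random
#' signs shared across subjects and sessions. When `dims` and `region` are
#' given, patterns span the whole grid with the codes planted only inside
#' `region`; otherwise all `n_voxels` carry the codes.
#'
#' @param n_subjects Number of subjects.
#' @param runs_per_condition,trials_per_run,matches_per_run Run structure.
#' @param n_voxels Number of voxels when no grid geometry is given.
#' @param category_amp,relevance_amp Per-voxel absolute code amplitudes.
#' @param attenuation Multiplier in `[0, 1]` applied to the relevance code in
#'   the disrupted session (1 = no disruption).
#' @param noise_sd Trial noise SD.
#' @param dims Optional grid dims (3 integers).
#' @param region Optional voxel coordinate matrix (see [cuboid_region()]);
#'   codes are planted there.
#' @param seed Master seed.
#' @return List with `subjects` (per subject: `control` and `disrupted`
#'   [pattern_set()]s), `cat_pattern`, `rel_pattern`, and `region_cols`
#'   (column indices of the planted region).
#' @export
simulate_pattern_cohort <- function(n_subjects = 8, runs_per_condition = 5,
                                    trials_per_run = 20, matches_per_run = 4,
                                    n_voxels = 27, category_amp = 0,
                                    relevance_amp = 0, attenuation = 1,
                                    noise_sd = 1, dims = NULL, region = NULL,
                                    seed = 1L) {
  design_cfg <- sim_config(n_subjects = n_subjects,
                           runs_per_condition = runs_per_condition,
                           trials_per_run = trials_per_run,
                           matches_per_run = matches_per_run,
                           grid_dims = c(1, 1, 1), regions = list(),
                           category_code = list(), relevance_code = list(),
                           disruption_factors = list(), seed = seed)
  if (!is.null(dims)) {
    V <- prod(dims)
    coords <- cuboid_region(seq_len(dims[1]), seq_len(dims[2]),
                            seq_len(dims[3]))
    # expand.grid order must match linear grid order
    coords <- coords[order(region_to_linear(coords, dims)), , drop = FALSE]
    region_cols <- if (is.null(region)) integer(0) else
      region_to_linear(region, dims)
  } else {
    V <- n_voxels
    coords <- NULL
    region_cols <- seq_len(V)
  }
  cat_pattern <- numeric(V)
  rel_pattern <- numeric(V)
  signs <- with_seed(seed + 101L,
                     matrix(sample(c(-1, 1), 2 * length(region_cols),
                                   replace = TRUE), ncol = 2))
  if (length(region_cols) > 0) {
    cat_pattern[region_cols] <- category_amp * signs[, 1]
    rel_pattern[region_cols] <- relevance_amp * signs[, 2]
  }

  subj_seeds <- child_seeds(seed, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sess_seeds <- child_seeds(subj_seeds[s], 2L)
    out <- list()
    for (i in 1:2) {
      tms <- c("control", "disrupted")[i]
      att <- if (tms == "disrupted") attenuation else 1
      run_seeds <- child_seeds(sess_seeds[i], 2L * runs_per_condition + 1L)
      conds <- rep(c("remember_faces", "remember_scenes"), runs_per_condition)
      sets <- lapply(seq_along(conds), function(r) {
        ev <- make_run_design(design_cfg, conds[r], seed = run_seeds[r],
                              run_id = sprintf("run-%02d", r),
                              tms_condition = tms)
        n <- nrow(ev)
        cat_sign <- ifelse(ev$category == "face", 1, -1)
        rel_sign <- ifelse(relevance_labels(ev) == "relevant", 1, -1)
        X <- with_seed(run_seeds[r] + 1L,
                       matrix(rnorm(n * V, 0, noise_sd), n, V)) +
          outer(cat_sign, cat_pattern) + outer(rel_sign, rel_pattern * att)
        info <- tibble(category = ev$category,
                       relevance = relevance_labels(ev),
                       run_id = attr(ev, "run_id"),
                       condition = attr(ev, "condition"),
                       tms_condition = tms, onset_s = ev$onset_s,
                       volume = NA_integer_)
        pattern_set(X, info, coords = coords, dims = dims)
      })
      out[[tms]] <- bind_pattern_sets(sets)
    }
    out
  })
  list(subjects = subjects, cat_pattern = cat_pattern,
       rel_pattern = rel_pattern, region_cols = region_cols, seed = seed)
}

#' Restrict a pattern set to a voxel subset
#'
#' @param patterns A [pattern_set()].
#' @param region Voxel coordinate matrix (rows x 3) or logical 3D array.
#' @return A [pattern_set()] restricted to those voxels.
#' @export
subset_pattern_set <- function(patterns, region) {
  if (is.null(patterns$coords)) {
    abort("pattern set lacks voxel coordinates.",
          class = "boldmvpa_invalid_argument")
  }
  if (is.array(region) && !is.matrix(region)) {
    region <- which(region, arr.ind = TRUE)
  }
  want <- region_to_linear(region, patterns$dims)
  have <- region_to_linear(patterns$coords, patterns$dims)
  cols <- match(want, have)
  if (anyNA(cols)) {
    abort("region contains voxels absent from the pattern set.",
          class = "boldmvpa_unknown_region")
  }
  pattern_set(patterns$X[, cols, drop = FALSE], patterns$info,
              coords = patterns$coords[cols, , drop = FALSE],
              dims = patterns$dims, voxel_size_mm = patterns$voxel_size_mm)
}
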
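#' Define a cuboid region on the simulation grid
#'
#' @param x,y,z Integer ranges of 1-based voxel indices along each axis.
#' @return An integer matrix with one row per voxel and columns x, y, z.
#' @examples
#' cuboid_region(1:3, 1:3, 1:2)
#' @export
cuboid_region <- function(x, y, z) {
  g <- expand.grid(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

region_to_linear <- function(region, grid_dims) {
  (region[, 1] - 1L) +
    grid_dims[1] * (region[, 2] - 1L) +
    grid_dims[1] * grid_dims[2] * (region[, 3] - 1L) + 1L
}

#' Simulation configuration for a synthetic BOLD cohort
#'
#' Builds the configuration object consumed by [simulate_run()] and
#' [simulate_cohort()]. The defaults emulate a two-session disruption experiment: per
#' subject and TMS session, five "Remember Faces" and five "Remember Scenes"
#' runs of 20 trials each (10 face / 10 scene), four one-back matches per
#' run, 600 ms stimuli with onset-to-onset gaps drawn from {3, 5, 7} s, and
#' TR = 1 s. Two multivoxel codes are planted in designated voxel regions: a
#' stimulus-category code (face = +1, scene = -1) and a goal-relevance code
#' (relevant = +1, irrelevant = -1). In the disrupted (stimulation) session
#' the planted code amplitude in regions listed in `disruption_factors` is
#' multiplied by the given factor in `[0, 1]` (1 = no disruption); by
#' default only the relevance code is attenuated.
#'
#' Scalar code amplitudes are expanded into fixed per-voxel signed patterns
#' (amplitude times a random +/-1 sign per voxel, drawn once from `seed`),
#' so every voxel carries the same absolute amplitude with a random sign --
#' the idealized multivoxel code the decoding analyses assume.
#'
#' @param n_subjects Number of subjects.
#' @param runs_per_condition Runs per task condition per session.
#' @param trials_per_run Trials per run (must be even; split half face /
#'   half scene).
#' @param matches_per_run One-back matches per run, all within the relevant
#'   category; must be <= relevant trials - 1.
#' @param iti_choices_s Allowed onset-to-onset gaps (s).
#' @param stim_duration_s Stimulus duration (s).
#' @param tr_s Repetition time (s).
#' @param grid_dims Integer vector of 3 voxel counts.
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param noise_sd SD of i.i.d. Gaussian measurement noise (signal units).
#' @param regions Named list of voxel-coordinate matrices (see
#'   [cuboid_region()]) registering the plantable regions.
#' @param category_code,relevance_code Named lists mapping a region id to a
#'   per-voxel signed amplitude pattern, or to a scalar amplitude that is
#'   expanded as described above.
#' @param disruption_factors Named list mapping region ids to multipliers in
#'   `[0, 1]` applied in the disrupted session.
#' @param disrupt_codes Which planted codes the disruption factor attenuates
#'   (default: only the relevance code).
#' @param drift_coeffs_range Range of absolute low-order polynomial drift
#'   coefficients per voxel (signs random).
#' @param motion_sd SD of the random-walk increments of the six motion
#'   traces.
#' @param motion_coef_sd SD of the per-voxel motion-coupling coefficients.
#' @param subject_amp_scale_sd SD (log scale) of the subject-specific
#'   multiplier applied to planted code amplitudes; induces across-subject
#'   variation that the behavior model taps.
#' @param behavior_model List with `baseline`, `gain`, `sd`, and `region`:
#'   behavioral accuracy = baseline + gain * subject amplitude scale *
#'   disruption factor of `region` + Gaussian noise, clipped to `[0, 1]`.
#'   Defaults reproduce mean accuracies near 0.93 (control) and 0.90
#'   (disrupted).
#' @param first_onset_s Onset of the first trial (s).
#' @param post_padding_s Seconds of rest appended after the last trial so
#'   late lag windows stay inside the run.
#' @param seed Master integer seed; every simulated artifact is a
#'   deterministic function of the configuration including this seed.
#' @return A `sim_config` object (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 2, grid_dims = c(12, 12, 8),
#'                   regions = list(v = cuboid_region(3:6, 3:6, 3:5)),
#'                   category_code = list(v = 0.4), relevance_code = list(),
#'                   disruption_factors = list(), seed = 1)
#' @export
sim_config <- function(n_subjects = 8,
                       runs_per_condition = 5,
                       trials_per_run = 20,
                       matches_per_run = 4,
                       iti_choices_s = c(3, 5, 7),
                       stim_duration_s = 0.6,
                       tr_s = 1,
                       grid_dims = c(24, 24, 16),
                       voxel_size_mm = 3.5,
                       noise_sd = 1,
                       regions = list(
                         visual = cuboid_region(8:13, 3:8, 5:9),
                         frontal = cuboid_region(8:13, 17:22, 8:12)
                       ),
                       category_code = list(visual = 0.028),
                       relevance_code = list(frontal = 0.028),
                       disruption_factors = list(frontal = 0.5),
                       disrupt_codes = "relevance",
                       drift_coeffs_range = c(0, 0.3),
                       motion_sd = 0.05,
                       motion_coef_sd = 0.1,
                       subject_amp_scale_sd = 0.25,
                       behavior_model = list(baseline = 0.873, gain = 0.056,
                                             sd = 0.01, region = "frontal"),
                       first_onset_s = 2,
                       post_padding_s = 12,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    runs_per_condition = as.integer(runs_per_condition),
    trials_per_run = as.integer(trials_per_run),
    matches_per_run = as.integer(matches_per_run),
    iti_choices_s = iti_choices_s,
    stim_duration_s = stim_duration_s,
    tr_s = tr_s,
    grid_dims = as.integer(grid_dims),
    voxel_size_mm = voxel_size_mm,
    noise_sd = noise_sd,
    regions = regions,
    category_code = category_code,
    relevance_code = relevance_code,
    disruption_factors = disruption_factors,
    disrupt_codes = disrupt_codes,
    drift_coeffs_range = drift_coeffs_range,
    motion_sd = motion_sd,
    motion_coef_sd = motion_coef_sd,
    subject_amp_scale_sd = subject_amp_scale_sd,
    behavior_model = behavior_model,
    first_onset_s = first_onset_s,
    post_padding_s = post_padding_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg <- expand_codes(cfg)
  validate_sim_config(cfg)
  cfg
}

# expand scalar code amplitudes into per-voxel signed patterns, drawn once
# from the config seed so codes are shared across subjects and sessions
expand_codes <- function(cfg) {
  expand_one <- function(code, which) {
    if (length(code) == 0) return(code)
    seeds <- child_seeds(cfg$seed + if (which == "category") 101L else 202L,
                         length(code))
    for (i in seq_along(code)) {
      rid <- names(code)[i]
      if (!rid %in% names(cfg$regions)) {
        abort(paste0("unknown region id '", rid, "' in ", which, "_code"),
              class = "boldmvpa_unknown_region")
      }
      nvox <- nrow(cfg$regions[[rid]])
      if (length(code[[i]]) == 1) {
        code[[i]] <- code[[i]] *
          with_seed(seeds[i], sample(c(-1, 1), nvox, replace = TRUE))
      } else if (length(code[[i]]) != nvox) {
        abort(paste0("code pattern for region '", rid, "' must have length 1 or ",
                     nvox), class = "boldmvpa_invalid_argument")
      }
    }
    code
  }
  cfg$category_code <- expand_one(cfg$category_code, "category")
  cfg$relevance_code <- expand_one(cfg$relevance_code, "relevance")
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$trials_per_run %% 2L != 0L) {
    abort("`trials_per_run` must be even (half face / half scene per run).",
          class = "boldmvpa_invalid_argument")
  }
  n_relevant <- cfg$trials_per_run %/% 2L
  if (cfg$matches_per_run > n_relevant - 1L) {
    abort("`matches_per_run` must be <= relevant trials per run - 1.",
          class = "boldmvpa_design_infeasible")
  }
  if (length(cfg$grid_dims) != 3 || any(cfg$grid_dims < 1)) {
    abort("`grid_dims` must be 3 positive voxel counts.",
          class = "boldmvpa_invalid_argument")
  }
  for (rid in names(cfg$disruption_factors)) {
    f <- cfg$disruption_factors[[rid]]
    if (!rid %in% names(cfg$regions)) {
      abort(paste0("unknown region id '", rid, "' in disruption_factors"),
            class = "boldmvpa_unknown_region")
    }
    if (f < 0 || f > 1) {
      abort("disruption multipliers must lie in [0, 1].",
            class = "boldmvpa_invalid_argument")
    }
  }
  for (rid in names(cfg$regions)) {
    reg <- cfg$regions[[rid]]
    if (any(reg < 1) || any(reg > matrix(cfg$grid_dims, nrow(reg), 3, byrow = TRUE))) {
      abort(paste0("region '", rid, "' has voxels outside the grid"),
            class = "boldmvpa_invalid_argument")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects x 2 sessions; %d runs/condition x %d trials (%d matches)\n",
              x$n_subjects, x$runs_per_condition, x$trials_per_run,
              x$matches_per_run))
  cat(sprintf("  grid %s @ %.1f mm, TR %.2g s, noise sd %.3g\n",
              paste(x$grid_dims, collapse = "x"), x$voxel_size_mm, x$tr_s,
              x$noise_sd))
  cat(sprintf("  regions: %s\n", paste(names(x$regions), collapse = ", ")))
  invisible(x)
}
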
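#' Simulate one BOLD run with planted multivoxel codes
#'
#' Forward model: each voxel's time series is the sum over trials of an
#' HRF-convolved boxcar scaled by the voxel's planted code amplitudes --
#' category amplitude times the trial's category sign (face = +1, scene =
#' -1) plus relevance amplitude times the trial's relevance sign (relevant =
#' +1, irrelevant = -1), the latter multiplied by the region's disruption
#' factor when the run belongs to the disrupted session -- plus low-order
#' polynomial drift, a linear combination of the run's six motion traces,
#' and i.i.d. Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param events Event table from [make_run_design()]; its `tms_condition`
#'   attribute decides whether disruption factors apply.
#' @param seed Integer seed for noise, drift, and motion draws.
#' @param amp_scale Subject-specific multiplier on all planted code
#'   amplitudes.
#' @return List with elements `vol` (a [volume4d()]) and `motion` (a T x 6
#'   tibble: x, y, z, roll, pitch, yaw).
#' @export
simulate_run <- function(cfg, events, seed = 1L, amp_scale = 1) {
  tr <- cfg$tr_s
  dur <- attr(events, "run_duration_s")
  n_t <- as.integer(round(dur / tr))
  tms <- attr(events, "tms_condition")
  dims <- cfg$grid_dims
  n_vox <- prod(dims)

  # trial drives on a fine grid, convolved with the canonical HRF
  dt <- tr / 10
  fine_len <- as.integer(round(dur / dt))
  t_fine <- (seq_len(fine_len) - 1) * dt
  rel <- relevance_labels(events)
  cat_sign <- ifelse(events$category == "face", 1, -1)
  rel_sign <- ifelse(rel == "relevant", 1, -1)
  box_of <- function(signs) {
    drive <- numeric(fine_len)
    for (i in seq_len(nrow(events))) {
      on <- events$onset_s[i]
      idx <- which(t_fine >= on & t_fine < on + events$duration_s[i])
      drive[idx] <- drive[idx] + signs[i]
    }
    drive
  }
  h <- double_gamma_hrf(dt, 32)
  conv_sample <- function(drive) {
    full <- stats::convolve(drive, rev(h), type = "open")[seq_len(fine_len)]
    vol_idx <- as.integer(round(((seq_len(n_t) - 1) * tr) / dt)) + 1L
    full[vol_idx]
  }
  cat_series <- conv_sample(box_of(cat_sign))
  rel_series <- conv_sample(box_of(rel_sign))

  with_seed(seed, {
    Y <- matrix(0, n_vox, n_t)
    add_code <- function(Y, code, series, which_code) {
      for (rid in names(code)) {
        amp <- code[[rid]] * amp_scale
        if (tms == "disrupted" && which_code %in% cfg$disrupt_codes &&
            rid %in% names(cfg$disruption_factors)) {
          amp <- amp * cfg$disruption_factors[[rid]]
        }
        lin <- region_to_linear(cfg$regions[[rid]], dims)
        Y[lin, ] <- Y[lin, ] + outer(amp, series)
      }
      Y
    }
    Y <- add_code(Y, cfg$category_code, cat_series, "category")
    Y <- add_code(Y, cfg$relevance_code, rel_series, "relevance")

    # polynomial drift (orders 1-3 over the run, coefficients with random
    # signs and magnitudes uniform in drift_coeffs_range)
    if (diff(range(cfg$drift_coeffs_range)) > 0 || max(cfg$drift_coeffs_range) > 0) {
      u <- seq(-1, 1, length.out = n_t)
      basis <- cbind(u, u^2, u^3)
      coef <- matrix(runif(n_vox * 3, cfg$drift_coeffs_range[1],
                           cfg$drift_coeffs_range[2]) *
                       sample(c(-1, 1), n_vox * 3, replace = TRUE),
                     n_vox, 3)
      Y <- Y + coef %*% t(basis)
    }

    # motion traces (per-parameter random walks) and their per-voxel coupling
    motion <- apply(matrix(rnorm(n_t * 6, 0, cfg$motion_sd), n_t, 6), 2, cumsum)
    if (cfg$motion_coef_sd > 0) {
      B <- matrix(rnorm(n_vox * 6, 0, cfg$motion_coef_sd), n_vox, 6)
      Y <- Y + B %*% t(motion)
    }

    if (cfg$noise_sd > 0) {
      Y <- Y + matrix(rnorm(n_vox * n_t, 0, cfg$noise_sd), n_vox, n_t)
    }

    motion_tbl <- as_tibble(as.data.frame(motion))
    names(motion_tbl) <- c("x", "y", "z", "roll", "pitch", "yaw")
    list(
      vol = volume4d(array(Y, dim = c(dims, n_t)), cfg$voxel_size_mm, tr,
                     t0_s = 0),
      motion = motion_tbl
    )
  })
}

#' Simulate a full two-session cohort
#'
#' Generates `n_subjects` subjects, each with a control and a disrupted
#' session of `runs_per_condition` "Remember Faces" plus
#' `runs_per_condition` "Remember Scenes" runs, and a behavioral accuracy
#' per subject and session. Each subject carries a log-normal amplitude
#' scale applied to all planted codes; behavioral accuracy increases with
#' that scale (times the designated region's disruption factor in the
#' disrupted session), so behavior correlates positively with the subject's
#' undisrupted relevance-code amplitude.
#'
#' @param cfg A [sim_config()]; `cfg$seed` determines everything.
#' @param out_dir Optional directory; when given, the cohort is also written
#'   to disk (NIfTI runs, TSV event/motion/behavior tables, mask volumes,
#'   JSON manifest) via [write_cohort()].
#' @return A `bold_cohort` object: list with `config`, `behavior` (tibble:
#'   subject, tms_condition, accuracy), `amp_scales`, and `subjects` --
#'   per subject, per session, a list of runs (each `events`, `vol`,
#'   `motion`).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  n <- cfg$n_subjects
  subj_seeds <- child_seeds(cfg$seed, n)
  amp_scales <- with_seed(cfg$seed + 7L,
                          exp(rnorm(n, 0, cfg$subject_amp_scale_sd)))
  bm <- cfg$behavior_model
  d_factor <- if (!is.null(bm$region) && bm$region %in% names(cfg$disruption_factors)) {
    cfg$disruption_factors[[bm$region]]
  } else 1
  behavior_noise <- with_seed(cfg$seed + 11L, rnorm(2L * n, 0, bm$sd))

  subjects <- vector("list", n)
  behavior <- list()
  k <- 0L
  for (s in seq_len(n)) {
    sessions <- list()
    run_seeds <- child_seeds(subj_seeds[s], 4L * cfg$runs_per_condition + 2L)
    rs <- 0L
    for (tms in c("control", "disrupted")) {
      k <- k + 1L
      acc <- bm$baseline +
        bm$gain * amp_scales[s] * (if (tms == "disrupted") d_factor else 1) +
        behavior_noise[k]
      acc <- min(max(acc, 0), 1)
      behavior[[k]] <- tibble(subject = sprintf("sub-%02d", s),
                              tms_condition = tms, accuracy = acc)
      runs <- list()
      conds <- rep(c("remember_faces", "remember_scenes"), cfg$runs_per_condition)
      for (r in seq_along(conds)) {
        rs <- rs + 1L
        ev <- make_run_design(cfg, conds[r], seed = run_seeds[rs],
                              run_id = sprintf("run-%02d", r),
                              tms_condition = tms, accuracy = acc)
        rs2 <- run_seeds[rs] + 1L
        runs[[r]] <- c(list(events = ev),
                       simulate_run(cfg, ev, seed = rs2,
                                    amp_scale = amp_scales[s]))
      }
      sessions[[tms]] <- runs
    }
    subjects[[s]] <- sessions
  }
  cohort <- structure(
    list(config = cfg, behavior = dplyr::bind_rows(behavior),
         amp_scales = amp_scales, subject_seeds = subj_seeds,
         subjects = stats::setNames(subjects, sprintf("sub-%02d", seq_len(n)))),
    class = "bold_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects x 2 sessions x %d runs\n",
              x$config$n_subjects, 2L * x$config$runs_per_condition))
  invisible(x)
}
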
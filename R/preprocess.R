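#' Build a run's GLM design matrix
#'
#' Columns: one HRF-convolved boxcar regressor per stimulus-category x
#' task-condition combination present in the run, the six motion parameters
#' as given, and six mutually orthogonal polynomial baseline columns (orders
#' 0--5: an intercept plus `stats::poly(, 5)`). The stimulus columns are
#' orthogonalized against the nuisance block (motion + baseline), so shared
#' variance -- notably the regressors' mean and slow-drift components -- is
#' attributed to the baseline and removed by [residualize_baseline()]; the
#' baseline-subtracted series is then exactly orthogonal to every nuisance
#' regressor.
#'
#' @param events Event table (see [make_run_design()]).
#' @param motion T x 6 data frame or matrix of motion parameters.
#' @param n_t Number of volumes T.
#' @param tr_s Repetition time (s).
#' @param t0_s Acquisition time of the first volume (s).
#' @return Numeric T x P matrix with attributes `roles` (character:
#'   "stimulus", "motion", "baseline") and column names.
#' @export
build_design_matrix <- function(events, motion, n_t, tr_s, t0_s = 0) {
  if (nrow(events) == 0 || all(events$duration_s <= 0)) {
    abort("event table yields an empty stimulus block.",
          class = "boldmvpa_empty_design")
  }
  motion <- as.matrix(motion)
  if (nrow(motion) != n_t) {
    abort(sprintf("motion table has %d rows but the run has %d volumes.",
                  nrow(motion), n_t), class = "boldmvpa_shape_error")
  }
  condition <- attr(events, "condition")
  run_end <- max(events$onset_s + events$duration_s)
  if (run_end > t0_s + n_t * tr_s) {
    abort("events extend past the end of the run.",
          class = "boldmvpa_shape_error")
  }

  dt <- tr_s / 10
  fine_len <- as.integer(ceiling((t0_s + n_t * tr_s) / dt))
  t_fine <- (seq_len(fine_len) - 1) * dt
  h <- double_gamma_hrf(dt, 32)
  vol_idx <- as.integer(round((t0_s + (seq_len(n_t) - 1) * tr_s) / dt)) + 1L

  cats <- sort(unique(events$category))
  stim <- sapply(cats, function(cc) {
    drive <- numeric(fine_len)
    for (i in which(events$category == cc)) {
      idx <- which(t_fine >= events$onset_s[i] &
                   t_fine < events$onset_s[i] + events$duration_s[i])
      drive[idx] <- drive[idx] + 1
    }
    stats::convolve(drive, rev(h), type = "open")[vol_idx]
  })
  colnames(stim) <- paste0("stim_", cats, "_", condition)

  poly_cols <- cbind(1, stats::poly(seq_len(n_t), 5))
  colnames(poly_cols) <- paste0("poly", 0:5)
  colnames(motion) <- c("x", "y", "z", "roll", "pitch", "yaw")

  nuis <- cbind(motion, poly_cols)
  stim <- stim - nuis %*% solve(crossprod(nuis), crossprod(nuis, stim))
  X <- cbind(stim, motion, poly_cols)
  zero_cols <- colnames(X)[colSums(abs(X)) == 0]
  if (length(zero_cols) > 0) {
    abort(paste0("design matrix has all-zero columns: ",
                 paste(zero_cols, collapse = ", ")),
          class = "boldmvpa_rank_deficient")
  }
  attr(X, "roles") <- c(rep("stimulus", ncol(stim)), rep("motion", 6),
                        rep("baseline", 6))
  X
}

#' Regress out and subtract the baseline (nuisance) component
#'
#' Fits the full design (stimulus + motion + polynomial baseline) per voxel
#' by ordinary least squares, then subtracts only the fitted motion +
#' polynomial component, retaining the stimulus-explained signal.
#'
#' @param vol A [volume4d()].
#' @param X Design matrix from [build_design_matrix()].
#' @return A [volume4d()] of the same shape.
#' @export
residualize_baseline <- function(vol, X) {
  n_t <- n_volumes(vol)
  if (nrow(X) != n_t) {
    abort(sprintf("design has %d rows but the run has %d volumes.",
                  nrow(X), n_t), class = "boldmvpa_shape_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "boldmvpa_rank_deficient")
  }
  Y <- as_time_by_voxel(vol)
  beta <- qr.coef(qrX, Y)
  nuis <- attr(X, "roles") %in% c("motion", "baseline")
  fitted_nuis <- X[, nuis, drop = FALSE] %*% beta[nuis, , drop = FALSE]
  matrix_to_volume(Y - fitted_nuis, vol)
}

#' Temporally z-score each voxel of a run
#'
#' Per voxel: subtract the temporal mean and divide by the sample SD.
#' Voxels with SD below `1e-12` are set to all zero and flagged in the
#' returned volume's `degenerate_voxels` attribute.
#'
#' @param vol A [volume4d()] with at least 2 volumes.
#' @return A [volume4d()].
#' @export
zscore_run <- function(vol) {
  if (n_volumes(vol) < 2) {
    abort("z-scoring needs at least 2 volumes.",
          class = "boldmvpa_invalid_argument")
  }
  Y <- as_time_by_voxel(vol)
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, sd)
  degenerate <- sdv < 1e-12
  Z <- sweep(Y, 2, mu, "-")
  Z[, !degenerate] <- sweep(Z[, !degenerate, drop = FALSE], 2,
                            sdv[!degenerate], "/")
  Z[, degenerate] <- 0
  out <- matrix_to_volume(Z, vol)
  attr(out, "degenerate_voxels") <- degenerate
  out
}

#' Extract single-volume trial patterns at a code-specific lag
#'
#' For each trial, selects the unique volume whose acquisition start time t
#' satisfies `onset + low <= t < onset + high` (half-open window; unique
#' whenever the window width does not exceed the TR), restricted to the mask
#' voxels.
#'
#' @param vol A (preprocessed) [volume4d()].
#' @param events Event table of the run.
#' @param lag_window_s Length-2 numeric `(low, high)` in seconds post onset.
#' @param mask Logical 3D array, or a voxels x 3 coordinate matrix; default
#'   all voxels.
#' @return A [pattern_set()] with per-trial labels derived from the event
#'   table (category; relevance via [relevance_labels()]).
#' @export
extract_trial_patterns <- function(vol, events, lag_window_s, mask = NULL) {
  d <- dim(vol$data)
  n_t <- d[4]
  t_vols <- vol$t0_s + (seq_len(n_t) - 1) * vol$tr_s
  low <- lag_window_s[1]; high <- lag_window_s[2]
  idx <- vapply(events$onset_s, function(on) {
    k <- which(t_vols >= on + low & t_vols < on + high)
    if (length(k) == 0) {
      abort(sprintf(paste0("lag window (%g, %g) s covers no volume for onset ",
                           "%g s (TR = %g s, run has %d volumes)"),
                    low, high, on, vol$tr_s, n_t),
            class = "boldmvpa_ambiguous_window")
    }
    if (length(k) > 1) {
      abort(sprintf("lag window (%g, %g) s covers %d volumes (TR = %g s)",
                    low, high, length(k), vol$tr_s),
            class = "boldmvpa_ambiguous_window")
    }
    k
  }, 1L)

  if (is.null(mask)) {
    mask_arr <- array(TRUE, dim = d[1:3])
  } else if (is.matrix(mask)) {
    mask_arr <- array(FALSE, dim = d[1:3])
    mask_arr[region_to_linear(mask, d[1:3])] <- TRUE
  } else {
    mask_arr <- mask
  }
  lin <- which(mask_arr)
  coords <- which(mask_arr, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")

  flat <- matrix(vol$data, prod(d[1:3]), n_t)
  X <- t(flat[lin, idx, drop = FALSE])
  info <- tibble(
    category = events$category,
    relevance = relevance_labels(events),
    run_id = attr(events, "run_id"),
    condition = attr(events, "condition"),
    tms_condition = attr(events, "tms_condition"),
    onset_s = events$onset_s,
    volume = idx
  )
  pattern_set(X, info, coords = coords, dims = d[1:3],
              voxel_size_mm = vol$voxel_size_mm)
}

#' Preprocess one run (nuisance GLM, baseline subtraction, z-scoring)
#'
#' @param run List with `vol`, `events`, `motion` (as produced by
#'   [simulate_cohort()] / [read_cohort()]).
#' @return The preprocessed [volume4d()].
#' @export
preprocess_run <- function(run) {
  n_t <- n_volumes(run$vol)
  X <- build_design_matrix(run$events, run$motion, n_t, run$vol$tr_s,
                           run$vol$t0_s)
  zscore_run(residualize_baseline(run$vol, X))
}

#' Preprocess a cohort and extract trial patterns for one code
#'
#' Runs the preprocessing chain on every run and pools the lag-window trial
#' patterns across a subject-session's runs.
#'
#' @param cohort A `bold_cohort` (or the list returned by [read_cohort()]).
#' @param code `"category"` (default lag window 5--6 s) or `"relevance"`
#'   (default 6--7 s).
#' @param lag_window_s Optional override of the code's lag window.
#' @param mask Optional mask (see [extract_trial_patterns()]).
#' @return Nested list: per subject, per session, one pooled
#'   [pattern_set()].
#' @export
extract_cohort_patterns <- function(cohort, code = c("category", "relevance"),
                                    lag_window_s = NULL, mask = NULL) {
  code <- match.arg(code)
  if (is.null(lag_window_s)) {
    lag_window_s <- if (code == "category") c(5, 6) else c(6, 7)
  }
  lapply(cohort$subjects, function(sessions) {
    lapply(sessions, function(runs) {
      sets <- lapply(runs, function(run) {
        extract_trial_patterns(preprocess_run(run), run$events, lag_window_s,
                               mask)
      })
      bind_pattern_sets(sets)
    })
  })
}
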
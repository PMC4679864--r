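#' Leave-one-run-pair-out cross-validation folds
#'
#' Pairs each "remember_faces" run with one "remember_scenes" run; every
#' fold's test set is exactly one such pair and every run appears as test
#' exactly once. Pairing is deterministic (sorted run order) unless
#' `random = TRUE`.
#'
#' @param run_table Data frame with columns `run_id` and `condition`
#'   (one row per run), e.g. `dplyr::distinct(patterns$info, run_id,
#'   condition)`.
#' @param random Pair runs at random instead of by sorted order.
#' @param seed Seed used only when `random = TRUE`.
#' @return A `cv_scheme`: tibble with columns `run_id`, `condition`, `fold`,
#'   and attribute `n_folds`.
#' @export
make_run_pair_folds <- function(run_table, random = FALSE, seed = 1L) {
  run_table <- as_tibble(run_table)[, c("run_id", "condition")]
  run_table <- dplyr::distinct(run_table)
  rf <- sort(run_table$run_id[run_table$condition == "remember_faces"])
  rs <- sort(run_table$run_id[run_table$condition == "remember_scenes"])
  if (length(rf) != length(rs)) {
    abort(sprintf("unequal run counts per task condition (%d vs %d).",
                  length(rf), length(rs)), class = "boldmvpa_pairing_error")
  }
  if (length(rf) < 2) {
    abort("need at least 2 run pairs (1 pair leaves an empty training set).",
          class = "boldmvpa_pairing_error")
  }
  if (random) {
    rs <- with_seed(seed, sample(rs))
  }
  folds <- dplyr::bind_rows(
    tibble(run_id = rf, condition = "remember_faces", fold = seq_along(rf)),
    tibble(run_id = rs, condition = "remember_scenes", fold = seq_along(rs))
  )
  out <- dplyr::arrange(folds, .data$fold, .data$condition)
  attr(out, "n_folds") <- length(rf)
  class(out) <- c("cv_scheme", class(out))
  out
}

# per-trial test-fold index for a pattern set under a cv scheme
trial_folds <- function(patterns, cv) {
  m <- match(patterns$info$run_id, cv$run_id)
  if (anyNA(m)) {
    abort("pattern set contains runs absent from the CV scheme.",
          class = "boldmvpa_pairing_error")
  }
  cv$fold[m]
}
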
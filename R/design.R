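#' Generate one run's event table
#'
#' Draws a pseudo-randomized trial sequence for a single run: equal numbers
#' of face and scene trials, stimuli of the task-relevant category separated
#' by 0--3 intervening irrelevant stimuli, onset-to-onset gaps drawn from
#' `iti_choices_s`, and exactly `matches_per_run` one-back matches, all
#' within the relevant category (a match requires a preceding relevant
#' trial, so the first relevant trial is never a match).
#'
#' @param cfg A [sim_config()].
#' @param condition Task condition of the run, `"remember_faces"` or
#'   `"remember_scenes"`; determines which category is relevant.
#' @param seed Integer seed for the sequence draw.
#' @param run_id Run identifier stored on the table.
#' @param tms_condition Session label stored on the table (`"control"` or
#'   `"disrupted"`).
#' @param accuracy Probability that each trial's response is correct;
#'   correctness labels are generated but never used to filter trials.
#' @return A tibble with columns onset_s, duration_s, category, match,
#'   correct, and attributes `condition`, `run_id`, `tms_condition`, and
#'   `run_duration_s`.
#' @examples
#' ev <- make_run_design(sim_config(seed = 1), "remember_faces", seed = 2)
#' table(ev$category)
#' @export
make_run_design <- function(cfg, condition = c("remember_faces", "remember_scenes"),
                            seed = 1L, run_id = "run-01",
                            tms_condition = "control", accuracy = 1) {
  condition <- match.arg(condition)
  n <- cfg$trials_per_run
  n_rel <- n %/% 2L
  n_irr <- n - n_rel
  with_seed(seed, {
    seq_rel <- draw_relevance_sequence(n_rel, n_irr)
    relevant_cat <- if (condition == "remember_faces") "face" else "scene"
    irrelevant_cat <- setdiff(c("face", "scene"), relevant_cat)
    category <- ifelse(seq_rel, relevant_cat, irrelevant_cat)
    # matches: choose among relevant trials that have a relevant predecessor
    rel_pos <- which(seq_rel)
    eligible <- rel_pos[-1]
    if (cfg$matches_per_run > length(eligible)) {
      abort("matches_per_run exceeds the number of eligible relevant trials.",
            class = "boldmvpa_design_infeasible")
    }
    match_pos <- sort(sample(eligible, cfg$matches_per_run))
    match <- rep("nonmatch", n)
    match[match_pos] <- "match"
    gaps <- sample(cfg$iti_choices_s, n - 1L, replace = TRUE)
    onset <- cfg$first_onset_s + c(0, cumsum(gaps))
    correct <- runif(n) < accuracy
    ev <- tibble(
      onset_s = onset,
      duration_s = cfg$stim_duration_s,
      category = category,
      match = match,
      correct = correct
    )
    attr(ev, "condition") <- condition
    attr(ev, "run_id") <- run_id
    attr(ev, "tms_condition") <- tms_condition
    attr(ev, "run_duration_s") <-
      ceiling((max(onset) + cfg$post_padding_s) / cfg$tr_s) * cfg$tr_s
    ev
  })
}

# sequence of relevant (TRUE) / irrelevant (FALSE) trials such that
# consecutive relevant trials are separated by 0..3 irrelevant ones
# (including before the first and after the last relevant trial)
draw_relevance_sequence <- function(n_rel, n_irr, max_gap = 3L,
                                    max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    gaps <- sample(0:max_gap, n_rel + 1L, replace = TRUE)
    if (sum(gaps) == n_irr) {
      out <- logical(0)
      for (g in seq_len(n_rel)) {
        out <- c(out, rep(FALSE, gaps[g]), TRUE)
      }
      out <- c(out, rep(FALSE, gaps[n_rel + 1L]))
      return(out)
    }
  }
  abort("could not place relevant trials with 0-3 intervening irrelevant ones.",
        class = "boldmvpa_design_infeasible")
}

#' Derive per-trial relevance labels from an event table
#'
#' A trial is relevant iff its category matches the run's task condition
#' (face in "remember_faces", scene in "remember_scenes").
#'
#' @param events An event table from [make_run_design()].
#' @return Character vector, `"relevant"` or `"irrelevant"` per trial.
#' @export
relevance_labels <- function(events) {
  condition <- attr(events, "condition")
  relevant_cat <- if (condition == "remember_faces") "face" else "scene"
  ifelse(events$category == relevant_cat, "relevant", "irrelevant")
}
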
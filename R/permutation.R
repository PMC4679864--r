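#' Pre-generate within-run label permutations
#'
#' Draws `n_perm` independent label vectors, each obtained by uniformly
#' shuffling the true labels within every run (runs are the exchangeability
#' blocks: per-run label counts are preserved). The identity permutation is
#' excluded. The same pre-generated set is meant to be reused across ROIs
#' and conditions so that permutation k is matched everywhere.
#'
#' @param labels Vector of true trial labels.
#' @param run_ids Vector of run membership, same length.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param id Identifier linking the same set across analyses.
#' @return A `permutation_set`: list with `labels` (n x n_perm matrix),
#'   `seed`, `id`.
#' @export
generate_label_permutations <- function(labels, run_ids, n_perm, seed = 1L,
                                        id = "perm") {
  if (n_perm < 1) {
    abort("`n_perm` must be >= 1.", class = "boldmvpa_invalid_argument")
  }
  n_perm <- as.integer(n_perm)
  n <- length(labels)
  stopifnot(length(run_ids) == n)
  runs <- split(seq_len(n), run_ids)
  if (any(vapply(runs, length, 1L) == 1L)) {
    warn("some runs contain a single trial; within-run shuffling is a no-op there.")
  }
  # a permutation can only differ from identity if some run has >1 distinct label
  can_differ <- any(vapply(runs, function(ix) length(unique(labels[ix])) > 1,
                           TRUE))
  perm <- with_seed(seed, {
    out <- matrix(labels, n, n_perm)
    for (k in seq_len(n_perm)) {
      repeat {
        lab_k <- labels
        for (ix in runs) {
          lab_k[ix] <- lab_k[sample(ix)]
        }
        if (!can_differ || !identical(lab_k, labels)) break
      }
      out[, k] <- lab_k
    }
    out
  })
  structure(list(labels = perm, seed = seed, id = id, n_perm = n_perm),
            class = "permutation_set")
}

#' @export
print.permutation_set <- function(x, ...) {
  cat(sprintf("<permutation_set> %d permutations of %d labels (id '%s', seed %d)\n",
              x$n_perm, nrow(x$labels), x$id, x$seed))
  invisible(x)
}

#' Group-level permutation null for ROI decoding accuracy
#'
#' For each pre-generated permutation k, every subject's classifier is
#' retrained and tested with the permuted labels (same CV folds), and the
#' subject accuracies are averaged to one group value; the n_perm group
#' values form the null distribution of group-mean accuracy.
#'
#' @param subject_patterns List of per-subject [pattern_set()]s.
#' @param perms List of per-subject `permutation_set`s sharing `n_perm` and
#'   `id`.
#' @param cv_schemes Optional list of per-subject `cv_scheme`s.
#' @param lambda L2 penalty of the logistic classifier.
#' @return List: `group_null` (length n_perm), `subject_null` (subjects x
#'   n_perm matrix).
#' @export
roi_group_null <- function(subject_patterns, perms, cv_schemes = NULL,
                           lambda = 1) {
  n_sub <- length(subject_patterns)
  ids <- unique(vapply(perms, function(p) p$id, ""))
  n_perms <- unique(vapply(perms, function(p) p$n_perm, 1L))
  if (length(ids) != 1 || length(n_perms) != 1) {
    abort("subjects' permutation sets are not aligned (id / n_perm mismatch).",
          class = "boldmvpa_alignment_error")
  }
  subject_null <- matrix(NA_real_, n_sub, n_perms)
  for (s in seq_len(n_sub)) {
    ps <- subject_patterns[[s]]
    cv <- if (is.null(cv_schemes)) {
      make_run_pair_folds(dplyr::distinct(ps$info, .data$run_id,
                                          .data$condition))
    } else cv_schemes[[s]]
    fold <- trial_folds(ps, cv)
    lev <- sort(unique(as.character(perms[[s]]$labels[, 1])))
    ymat <- matrix(as.integer(perms[[s]]$labels == lev[2]),
                   nrow(perms[[s]]$labels), n_perms)
    for (k in seq_len(n_perms)) {
      check_folds_two_class(ymat[, k], fold, attr(cv, "n_folds"))
    }
    subject_null[s, ] <- logreg_cv_batch(ps$X, ymat, fold,
                                         attr(cv, "n_folds"), lambda)
  }
  list(group_null = colMeans(subject_null), subject_null = subject_null)
}

#' Empirical p-value of an observed statistic against a null distribution
#'
#' Default rule: the fraction of null values strictly exceeding the observed
#' value, `p = #(null > observed) / n`. `method = "add_one"` uses the
#' positively biased `(k + 1) / (n + 1)` variant.
#'
#' @param null Numeric vector of null values (nonempty).
#' @param observed Observed scalar.
#' @param method `"fraction_greater"` (default) or `"add_one"`.
#' @return The empirical p-value.
#' @examples
#' empirical_p(c(0.4, 0.5, 0.6, 0.7), 0.65) # 0.25
#' @export
empirical_p <- function(null, observed,
                        method = c("fraction_greater", "add_one")) {
  method <- match.arg(method)
  if (length(null) == 0 || !all(is.finite(null))) {
    abort("`null` must be a nonempty vector of finite values.",
          class = "boldmvpa_invalid_argument")
  }
  k <- sum(null > observed)
  if (method == "fraction_greater") k / length(null)
  else (k + 1) / (length(null) + 1)
}

#' Above-chance ROI decoding test (group permutation)
#'
#' Combines observed per-subject accuracies and a [roi_group_null()] into a
#' group-mean accuracy, its empirical p, and a Bonferroni-corrected p for a
#' stated family size.
#'
#' @param observed Per-subject observed accuracies.
#' @param group_null Null vector of group-mean accuracies.
#' @param n_tests Bonferroni family size (number of ROI x condition tests in
#'   the invocation).
#' @param method Passed to [empirical_p()].
#' @return An `mvpa_perm_test` object (supports [tidy()]/[glance()]).
#' @export
above_chance_test <- function(observed, group_null, n_tests = 1,
                              method = "fraction_greater") {
  obs <- mean(observed)
  p <- empirical_p(group_null, obs, method)
  structure(list(observed = obs, null = group_null, p = p,
                 p_bonferroni = min(1, p * n_tests), n_tests = n_tests,
                 kind = "group-mean-accuracy"),
            class = "mvpa_perm_test")
}

#' Matched-permutation test for a condition difference in decoding accuracy
#'
#' For permutation k the null difference is the across-subject mean of
#' (control null accuracy k - disrupted null accuracy k), using the *same*
#' pre-generated permutation sets in both conditions; the observed
#' difference is the across-subject mean of (control observed - disrupted
#' observed); p is the fraction of null differences exceeding the observed
#' difference (one-sided: control > disrupted).
#'
#' @param ctrl_null,tms_null Subjects x n_perm matrices of per-subject null
#'   accuracies (from [roi_group_null()]`$subject_null`).
#' @param ctrl_obs,tms_obs Per-subject observed accuracies.
#' @param n_tests Bonferroni family size.
#' @param method Passed to [empirical_p()].
#' @return An `mvpa_perm_test` with elements `observed` (difference), `null`
#'   (length n_perm), `p`, `p_bonferroni`.
#' @export
tms_difference_test <- function(ctrl_null, tms_null, ctrl_obs, tms_obs,
                                n_tests = 1, method = "fraction_greater") {
  ctrl_null <- rbind(ctrl_null)
  tms_null <- rbind(tms_null)
  if (!all(dim(ctrl_null) == dim(tms_null)) ||
      length(ctrl_obs) != length(tms_obs) ||
      nrow(ctrl_null) != length(ctrl_obs)) {
    abort("control and disrupted inputs are not aligned (subjects / n_perm).",
          class = "boldmvpa_alignment_error")
  }
  null_diff <- colMeans(ctrl_null - tms_null)
  obs_diff <- mean(ctrl_obs - tms_obs)
  p <- empirical_p(null_diff, obs_diff, method)
  structure(list(observed = obs_diff, null = null_diff, p = p,
                 p_bonferroni = min(1, p * n_tests), n_tests = n_tests,
                 kind = "condition-difference"),
            class = "mvpa_perm_test")
}

#' @export
print.mvpa_perm_test <- function(x, ...) {
  cat(sprintf("<mvpa_perm_test> %s: observed %.4f, p = %.4g (Bonferroni x%d: %.4g)\n",
              x$kind, x$observed, x$p, x$n_tests, x$p_bonferroni))
  invisible(x)
}

#' @rdname above_chance_test
#' @param x An `mvpa_perm_test`.
#' @param ... Unused.
#' @method tidy mvpa_perm_test
#' @export
tidy.mvpa_perm_test <- function(x, ...) {
  tibble(kind = x$kind, observed = x$observed, p_value = x$p,
         p_bonferroni = x$p_bonferroni, n_perm = length(x$null),
         n_tests = x$n_tests)
}

#' @rdname above_chance_test
#' @method glance mvpa_perm_test
#' @export
glance.mvpa_perm_test <- function(x, ...) tidy(x)

#' Plot a permutation null with the observed statistic
#'
#' @param object An `mvpa_perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvpa_perm_test
#' @export
autoplot.mvpa_perm_test <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$kind, y = "count",
                  title = sprintf("observed = %.3f, p = %.3g",
                                  object$observed, object$p)) +
    ggplot2::theme_minimal()
}
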
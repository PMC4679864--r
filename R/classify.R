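#' Gaussian Naive Bayes fit-and-predict
#'
#' Per feature, class-conditional Gaussians with class means and a pooled
#' within-class variance (floored at `var_floor`); prediction is the argmax
#' of summed per-feature log-likelihood plus the log class prior (priors
#' from training frequencies). Exact log-likelihood ties go to the
#' lexicographically smaller class label.
#'
#' @param train_x,test_x Numeric matrices (trials x features).
#' @param train_labels Vector of two class labels, >= 2 training trials per
#'   class.
#' @param var_floor Variance floor (default `1e-6`).
#' @return Character vector of predicted labels with attribute
#'   `prop_floored` (fraction of features whose pooled variance was
#'   floored); a warning is raised when that fraction exceeds 0.5.
#' @export
gnb_fit_predict <- function(train_x, train_labels, test_x, var_floor = 1e-6) {
  lev <- sort(unique(as.character(train_labels)))
  if (length(lev) != 2) {
    abort("training labels must take exactly two values.",
          class = "boldmvpa_invalid_argument")
  }
  n_c <- table(factor(train_labels, levels = lev))
  if (any(n_c < 2)) {
    abort("need at least 2 training trials per class.",
          class = "boldmvpa_invalid_argument")
  }
  i0 <- train_labels == lev[1]
  m0 <- colMeans(train_x[i0, , drop = FALSE])
  m1 <- colMeans(train_x[!i0, , drop = FALSE])
  ss0 <- colSums(sweep(train_x[i0, , drop = FALSE], 2, m0)^2)
  ss1 <- colSums(sweep(train_x[!i0, , drop = FALSE], 2, m1)^2)
  v <- (ss0 + ss1) / (nrow(train_x) - 2)
  floored <- v < var_floor
  v[floored] <- var_floor
  if (mean(floored) > 0.5) {
    warn(sprintf("pooled variance floored on %.0f%% of features",
                 100 * mean(floored)))
  }
  log_prior <- log(as.numeric(n_c) / nrow(train_x))
  log_norm <- 0.5 * sum(log(2 * pi * v))
  ll <- function(m, lp) {
    -0.5 * as.numeric(sweep(test_x, 2, m)^2 %*% (1 / v)) - log_norm + lp
  }
  ll0 <- ll(m0, log_prior[1])
  ll1 <- ll(m1, log_prior[2])
  pred <- ifelse(ll1 > ll0, lev[2], lev[1]) # tie -> smaller label
  attr(pred, "prop_floored") <- mean(floored)
  pred
}

#' Cross-validated ROI decoding with L2-regularized logistic regression
#'
#' Per fold, fits a binary logistic regression with an L2 penalty `lambda`
#' on the weights (intercept unpenalized) by Newton iterations (convergence:
#' gradient norm below `tol`), predicts held-out trials at probability
#' threshold 0.5, and returns the unweighted mean accuracy across folds.
#'
#' @param patterns A [pattern_set()].
#' @param code Which label to decode: `"category"` or `"relevance"`.
#' @param cv A `cv_scheme` from [make_run_pair_folds()]; defaults to the
#'   sorted run-pair folds of `patterns`.
#' @param lambda L2 penalty (default 1).
#' @param tol,maxit Newton convergence controls.
#' @return An `mvpa_decoding` object: mean accuracy, per-fold accuracies,
#'   and metadata. Supports [tidy()] and [glance()].
#' @export
l2_logreg_cv_accuracy <- function(patterns, code = c("category", "relevance"),
                                  cv = NULL, lambda = 1, tol = 1e-8,
                                  maxit = 200) {
  code <- match.arg(code)
  if (is.null(cv)) {
    cv <- make_run_pair_folds(dplyr::distinct(patterns$info, .data$run_id,
                                              .data$condition))
  }
  lab <- code_labels(patterns, code)
  fold <- trial_folds(patterns, cv)
  n_folds <- attr(cv, "n_folds")
  check_folds_two_class(lab$y, fold, n_folds)
  res <- cpp_logreg_cv(patterns$X, matrix(lab$y, ncol = 1), fold, n_folds,
                       lambda, tol, maxit)
  if (!all(res$converged)) {
    bad <- which(!res$converged[1, ])
    abort(sprintf("logistic regression did not converge in folds %s (lambda = %g, maxit = %d)",
                  paste(bad, collapse = ", "), lambda, maxit),
          class = "boldmvpa_convergence_error")
  }
  fold_acc <- as.numeric(res$acc[1, ])
  structure(list(
    mean_accuracy = mean(fold_acc),
    fold_accuracies = tibble(fold = seq_len(n_folds), accuracy = fold_acc),
    code = code, lambda = lambda, levels = lab$levels,
    n_trials = nrow(patterns$X), n_voxels = ncol(patterns$X)
  ), class = "mvpa_decoding")
}

check_folds_two_class <- function(y, fold, n_folds) {
  for (f in seq_len(n_folds)) {
    tr <- y[fold != f]
    if (length(unique(tr)) < 2) {
      abort(sprintf("training set of fold %d contains a single class.", f),
            class = "boldmvpa_invalid_fold")
    }
  }
  invisible(TRUE)
}

# batched CV accuracies for a matrix of label vectors (used by the
# permutation machinery); returns mean-over-fold accuracy per label set
logreg_cv_batch <- function(X, label_matrix, fold, n_folds, lambda = 1,
                            tol = 1e-8, maxit = 200) {
  res <- cpp_logreg_cv(X, label_matrix, fold, n_folds, lambda, tol, maxit)
  if (!all(res$converged)) {
    abort("logistic regression did not converge for some permutations.",
          class = "boldmvpa_convergence_error")
  }
  rowMeans(res$acc)
}

#' @export
print.mvpa_decoding <- function(x, ...) {
  cat(sprintf("<mvpa_decoding> %s code: mean accuracy %.3f over %d folds (lambda = %g)\n",
              x$code, x$mean_accuracy, nrow(x$fold_accuracies), x$lambda))
  invisible(x)
}

#' @rdname l2_logreg_cv_accuracy
#' @param x An `mvpa_decoding` object.
#' @param ... Unused.
#' @method tidy mvpa_decoding
#' @export
tidy.mvpa_decoding <- function(x, ...) {
  dplyr::mutate(x$fold_accuracies, code = x$code)
}

#' @rdname l2_logreg_cv_accuracy
#' @method glance mvpa_decoding
#' @export
glance.mvpa_decoding <- function(x, ...) {
  tibble(code = x$code, mean_accuracy = x$mean_accuracy,
         n_folds = nrow(x$fold_accuracies), lambda = x$lambda,
         n_trials = x$n_trials, n_voxels = x$n_voxels)
}
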
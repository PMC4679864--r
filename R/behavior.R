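#' Spearman rank correlation with exact permutation p for small samples
#'
#' Rank correlation with average ranks for ties. For n <= 9 the two-sided
#' p-value is computed from the exact permutation distribution (all n!
#' assignments of the y ranks); for larger n the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df is used.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return A tibble with columns `rho`, `p_value`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n < 4 || length(y) != n) {
    abort("`x` and `y` must be paired vectors with n >= 4.",
          class = "boldmvpa_invalid_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a constant vector.",
          class = "boldmvpa_undefined_correlation")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    # rho of each permuted assignment via cross-products
    num <- matrix(ryc[perms], nrow(perms), n) %*% rxc
    rho_perm <- as.numeric(num) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}

# matrix of all permutations of 1:n (n! rows)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, setdiff(seq_len(n), pos)] <- sub
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Median-split Welch t-test of a decoding effect by behavioral impairment
#'
#' Splits subjects at the median behavioral accuracy decrement (ties at the
#' median: larger values go to the "most impaired" group; odd n: the median
#' subject is excluded) and compares the decoding metric between the most-
#' and least-impaired groups with Welch's unequal-variance t-test
#' (fractional degrees of freedom).
#'
#' @param decrements Per-subject behavioral accuracy drops (control minus
#'   disrupted).
#' @param effects Per-subject decoding metric to compare between groups.
#' @return A tibble with `t`, `df`, `p_value`, group sizes and means.
#' @export
median_split_welch <- function(decrements, effects) {
  n <- length(decrements)
  if (n < 4 || length(effects) != n) {
    abort("need paired vectors with n >= 4.", class = "boldmvpa_invalid_argument")
  }
  ord <- order(decrements, decreasing = TRUE)
  n_half <- n %/% 2L
  most <- ord[seq_len(n_half)]
  least <- ord[(n - n_half + 1L):n]
  if (length(most) < 2 || length(least) < 2) {
    abort("each median-split group needs >= 2 subjects.",
          class = "boldmvpa_insufficient_group")
  }
  ht <- t.test(effects[most], effects[least], var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n_most = length(most), n_least = length(least),
         mean_most = mean(effects[most]), mean_least = mean(effects[least]))
}
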
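#' Define functional ROIs from subject accuracy maps
#'
#' At each voxel valid in all subjects, tests the across-subject mean
#' decoding accuracy against the 50% chance level with a one-sample,
#' one-sided (greater) t-test, applies Benjamini-Hochberg FDR control at
#' level `q` over the valid voxels, and returns the surviving voxels as the
#' ROI mask together with the mean accuracy map inside the mask. Voxels with
#' zero across-subject variance have an undefined t statistic and are
#' excluded with a warning.
#'
#' @param maps List of per-subject [accuracy_map()]s (or 3D arrays with
#'   `NaN` outside valid centers) on a common grid, typically smoothed.
#' @param q FDR level (default 1e-4).
#' @param chance Chance accuracy (default 0.5).
#' @return List with `mask` (logical 3D array), `mean_map` (mean accuracy,
#'   `NaN` outside the mask), and `stats` (tibble: voxel coordinates, t, p,
#'   p_fdr for all valid voxels).
#' @export
define_functional_rois <- function(maps, q = 1e-4, chance = 0.5) {
  arrs <- lapply(maps, function(m) if (inherits(m, "accuracy_map")) m$values else m)
  n_sub <- length(arrs)
  if (n_sub < 3) {
    abort("need at least 3 subjects for the group t-test.",
          class = "boldmvpa_invalid_argument")
  }
  d <- dim(arrs[[1]])
  A <- vapply(arrs, as.numeric, numeric(prod(d))) # voxels x subjects
  valid <- rowSums(is.finite(A)) == n_sub
  m <- rowMeans(A)
  s <- apply(A, 1, sd)
  zero_var <- valid & s < 1e-14
  if (any(zero_var)) {
    warn(sprintf("%d voxels have zero across-subject variance; excluded.",
                 sum(zero_var)))
    valid <- valid & !zero_var
  }
  tstat <- rep(NA_real_, length(m))
  tstat[valid] <- (m[valid] - chance) / (s[valid] / sqrt(n_sub))
  pval <- rep(NA_real_, length(m))
  pval[valid] <- pt(tstat[valid], df = n_sub - 1, lower.tail = FALSE)
  p_fdr <- rep(NA_real_, length(m))
  p_fdr[valid] <- p.adjust(pval[valid], method = "BH")
  mask <- array(FALSE, dim = d)
  mask[valid & p_fdr <= q] <- TRUE
  mean_map <- array(NaN, dim = d)
  mean_map[mask] <- m[mask]
  idx <- which(array(valid, dim = d), arr.ind = TRUE)
  stats_tbl <- tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                      mean_accuracy = m[valid], t = tstat[valid],
                      p = pval[valid], p_fdr = p_fdr[valid],
                      in_mask = mask[valid])
  list(mask = mask, mean_map = mean_map, stats = stats_tbl, q = q,
       n_subjects = n_sub)
}
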
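#' Full-pipeline configuration
#'
#' Houses all fixed analysis constants: code-specific lag windows (category
#' 5--6 s, relevance 6--7 s post onset), classifier settings, searchlight
#' edges (3 for ROI definition, 5 for the condition-difference analysis),
#' smoothing FWHM (8 mm), inference counts and alpha levels (voxelwise
#' 0.005, cluster 0.005, FDR q 1e-4), and the master seed.
#'
#' @param sim A [sim_config()].
#' @param lag_windows Named list of lag windows (s) per code.
#' @param lambda L2 penalty of the ROI classifier.
#' @param rois Named list of ROI voxel-coordinate matrices; defaults to the
#'   simulation's region registry.
#' @param codes Codes analyzed at the ROI level.
#' @param searchlight_code Code analyzed in the whole-volume difference
#'   searchlight.
#' @param edge_roi,edge_diff Searchlight cube edges.
#' @param fwhm_mm Smoothing FWHM (mm).
#' @param n_perm,n_null,n_boot Inference counts (study-scale defaults 1000 /
#'   100 / 100000; scale down for desk use).
#' @param voxel_alpha,cluster_alpha,fdr_q Alpha levels.
#' @param seed Master pipeline seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            lag_windows = list(category = c(5, 6),
                                               relevance = c(6, 7)),
                            lambda = 1,
                            rois = NULL,
                            codes = c("category", "relevance"),
                            searchlight_code = "relevance",
                            edge_roi = 3, edge_diff = 5, fwhm_mm = 8,
                            n_perm = 1000, n_null = 100, n_boot = 1e5,
                            voxel_alpha = 0.005, cluster_alpha = 0.005,
                            fdr_q = 1e-4, seed = 1L) {
  stopifnot(n_perm >= 1, n_null >= 1, n_boot >= 1)
  for (a in c(voxel_alpha, cluster_alpha, fdr_q)) {
    stopifnot(a > 0, a < 1)
  }
  if (is.null(rois)) rois <- sim$regions
  structure(list(sim = sim, lag_windows = lag_windows, lambda = lambda,
                 rois = rois, codes = codes,
                 searchlight_code = searchlight_code,
                 edge_roi = edge_roi, edge_diff = edge_diff,
                 fwhm_mm = fwhm_mm, n_perm = n_perm, n_null = n_null,
                 n_boot = n_boot, voxel_alpha = voxel_alpha,
                 cluster_alpha = cluster_alpha, fdr_q = fdr_q,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full simulate - preprocess - decode - infer pipeline
#'
#' Simulates a cohort, preprocesses every run, decodes each configured code
#' in each ROI per subject and session, runs the three inference tiers
#' (above-chance permutation tests per ROI and session with Bonferroni
#' correction, matched-permutation condition-difference tests, and the
#' bootstrap cluster-corrected whole-volume searchlight difference), and the
#' brain-behavior statistics (Spearman correlation between disrupted-session
#' behavioral accuracy and relevance decoding; median-split Welch t-test of
#' the behavioral decrement against the decoding difference).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional report directory; when given, writes the JSON
#'   stats report, the cluster TSV, the surviving-cluster mask NIfTI, and a
#'   provenance manifest.
#' @return An `mvpa_report` list; see components in the source and the
#'   package vignette.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- config$sim
  n_sub <- cfg$n_subjects
  seeds <- child_seeds(config$seed, 6L)

  cohort <- simulate_cohort(cfg)

  # preprocess + extract full-grid patterns per code
  patterns <- lapply(config$lag_windows[config$codes], function(w) NULL)
  full <- list()
  for (code in config$codes) {
    full[[code]] <- extract_cohort_patterns(cohort, code,
                                            config$lag_windows[[code]])
  }

  conditions <- c("control", "disrupted")
  roi_results <- list()
  diff_results <- list()
  family_size <- length(config$rois) * length(config$codes) * 2L
  perm_seeds <- child_seeds(seeds[1], n_sub * length(config$codes))
  k <- 0L
  for (code in config$codes) {
    # matched permutation sets: one per subject x condition, same seed per
    # subject across conditions so permutation k is paired
    k <- k + 1L
    obs <- list(); nulls <- list()
    for (roi_name in names(config$rois)) {
      roi <- config$rois[[roi_name]]
      for (cond in conditions) {
        ps_list <- lapply(full[[code]], function(sess) {
          subset_pattern_set(sess[[cond]], roi)
        })
        perms <- lapply(seq_len(n_sub), function(s) {
          info <- ps_list[[s]]$info
          generate_label_permutations(info[[code]], info$run_id,
                                      config$n_perm,
                                      seed = perm_seeds[(k - 1L) * n_sub + s],
                                      id = paste0(code, "-perm"))
        })
        obs_acc <- vapply(ps_list, function(ps) {
          l2_logreg_cv_accuracy(ps, code, lambda = config$lambda)$mean_accuracy
        }, 1)
        nl <- roi_group_null(ps_list, perms, lambda = config$lambda)
        test <- above_chance_test(obs_acc, nl$group_null, family_size)
        roi_results[[paste(code, roi_name, cond, sep = ".")]] <-
          list(code = code, roi = roi_name, tms_condition = cond,
               subject_accuracies = obs_acc, test = test,
               subject_null = nl$subject_null)
        obs[[cond]] <- obs_acc
        nulls[[cond]] <- nl$subject_null
      }
      dt <- tms_difference_test(nulls$control, nulls$disrupted, obs$control,
                                obs$disrupted,
                                n_tests = length(config$rois) * length(config$codes))
      diff_results[[paste(code, roi_name, sep = ".")]] <-
        list(code = code, roi = roi_name, test = dt,
             control = obs$control, disrupted = obs$disrupted)
    }
  }

  # whole-volume searchlight condition difference
  sl_code <- config$searchlight_code
  sl_seeds <- child_seeds(seeds[2], n_sub)
  true_diff <- list(); null_diff <- list()
  for (s in seq_len(n_sub)) {
    maps <- lapply(conditions, function(cond) {
      ps <- full[[sl_code]][[s]][[cond]]
      lab <- code_labels(ps, sl_code)
      perm <- generate_label_permutations(ps$info[[sl_code]], ps$info$run_id,
                                          config$n_null, seed = sl_seeds[s],
                                          id = "sl-null")
      lev <- lab$levels
      labmat <- cbind(lab$y, matrix(as.integer(perm$labels == lev[2]),
                                    nrow(perm$labels)))
      searchlight_batch(ps, labmat, cube_edge = config$edge_diff)
    })
    smooth1 <- function(m) smooth_gaussian(m, config$fwhm_mm, cfg$voxel_size_mm)
    true_diff[[s]] <- smooth1(maps[[1]]$maps[[1]] - maps[[2]]$maps[[1]])
    null_diff[[s]] <- lapply(seq_len(config$n_null) + 1L, function(j) {
      smooth1(maps[[1]]$maps[[j]] - maps[[2]]$maps[[j]])
    })
  }
  sl_test <- searchlight_group_difference(true_diff, null_diff,
                                          n_boot = config$n_boot,
                                          voxel_alpha = config$voxel_alpha,
                                          cluster_alpha = config$cluster_alpha,
                                          seed = seeds[3])

  # behavior: correlate disrupted-session accuracy with disrupted relevance
  # decoding in the first relevance ROI; median-split on the decrement
  beh <- tidyr::pivot_wider(cohort$behavior, names_from = "tms_condition",
                            values_from = "accuracy")
  rel_roi <- names(config$rois)[length(config$rois)]
  rel_key <- paste("relevance", rel_roi, sep = ".")
  behavior_stats <- NULL
  if ("relevance" %in% config$codes && rel_key %in% names(diff_results)) {
    dec_dis <- diff_results[[rel_key]]$disrupted
    spear <- spearman_corr(beh$disrupted, dec_dis)
    decrement <- beh$control - beh$disrupted
    effect <- diff_results[[rel_key]]$control - diff_results[[rel_key]]$disrupted
    welch <- median_split_welch(decrement, effect)
    behavior_stats <- list(spearman = spear, median_split = welch,
                           roi = rel_roi)
  }

  report <- structure(list(
    schema_version = "1.0",
    config = config,
    config_hash = rlang::hash(config),
    behavior = cohort$behavior,
    roi_results = roi_results,
    diff_results = diff_results,
    searchlight = sl_test,
    behavior_stats = behavior_stats,
    seeds = list(master = config$seed, stage = seeds)
  ), class = "mvpa_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Summarize an experiment report as tidy tables
#'
#' @param x An `mvpa_report`.
#' @param ... Unused.
#' @return A tibble with one row per ROI x condition x code test plus the
#'   difference tests.
#' @method tidy mvpa_report
#' @export
tidy.mvpa_report <- function(x, ...) {
  above <- dplyr::bind_rows(lapply(x$roi_results, function(r) {
    dplyr::mutate(tidy(r$test), code = r$code, roi = r$roi,
                  tms_condition = r$tms_condition)
  }))
  diffs <- dplyr::bind_rows(lapply(x$diff_results, function(r) {
    dplyr::mutate(tidy(r$test), code = r$code, roi = r$roi,
                  tms_condition = NA_character_)
  }))
  dplyr::bind_rows(above, diffs)
}

#' @export
print.mvpa_report <- function(x, ...) {
  cat("<mvpa_report>\n")
  print(tidy(x), n = Inf)
  cat(sprintf("searchlight: %d surviving cluster(s)\n",
              sum(x$searchlight$clusters$survives)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stats <- list(
    schema_version = report$schema_version,
    config_hash = report$config_hash,
    seeds = report$seeds,
    tests = lapply(report$roi_results, function(r) {
      list(code = r$code, roi = r$roi, tms_condition = r$tms_condition,
           group_accuracy = r$test$observed, p = r$test$p,
           p_bonferroni = r$test$p_bonferroni, n_tests = r$test$n_tests)
    }),
    differences = lapply(report$diff_results, function(r) {
      list(code = r$code, roi = r$roi, observed_difference = r$test$observed,
           p = r$test$p, p_bonferroni = r$test$p_bonferroni)
    }),
    searchlight = as.list(glance(report$searchlight)),
    behavior = if (!is.null(report$behavior_stats)) list(
      spearman_rho = report$behavior_stats$spearman$rho,
      spearman_p = report$behavior_stats$spearman$p_value,
      welch_t = report$behavior_stats$median_split$t,
      welch_df = report$behavior_stats$median_split$df,
      welch_p = report$behavior_stats$median_split$p_value
    ) else NULL
  )
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(as.data.frame(report$searchlight$clusters),
                   file.path(out_dir, "clusters.tsv"))
  surv <- report$searchlight$binary_map
  lab <- attr(report$searchlight$clusters, "labels")
  keep <- report$searchlight$clusters$cluster[report$searchlight$clusters$survives]
  surviving_mask <- array(lab %in% keep, dim = dim(lab))
  write_mask_nifti(surviving_mask, report$config$sim$voxel_size_mm,
                   file.path(out_dir, "surviving_clusters.nii.gz"))
  readr::write_tsv(report$behavior, file.path(out_dir, "behavior.tsv"))
  invisible(out_dir)
}
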
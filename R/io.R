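#' Write a simulated cohort to a dataset directory
#'
#' Layout: one NIfTI run plus `_events.tsv` (columns onset, duration,
#' category, match, correct) and 6-column `_motion.tsv` per run under
#' `sub-XX/<session>/`, 3D region and brain masks under `masks/`, a
#' `behavior.tsv` table (subject, tms_condition, accuracy), and a
#' `manifest.json` recording seeds, run attributes, and the region registry.
#'
#' @param cohort A `bold_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  cfg <- cohort$config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  runs_index <- list()
  for (sub in names(cohort$subjects)) {
    for (tms in names(cohort$subjects[[sub]])) {
      rdir <- file.path(out_dir, sub, tms)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      runs <- cohort$subjects[[sub]][[tms]]
      for (run in runs) {
        rid <- attr(run$events, "run_id")
        base <- file.path(rdir, rid)
        write_volume(run$vol, paste0(base, "_bold.nii.gz"))
        ev <- run$events
        names(ev) <- c("onset", "duration", "category", "match", "correct")
        readr::write_tsv(ev, paste0(base, "_events.tsv"))
        readr::write_tsv(run$motion, paste0(base, "_motion.tsv"))
        runs_index[[length(runs_index) + 1L]] <- list(
          subject = sub, tms_condition = tms, run_id = rid,
          condition = attr(run$events, "condition"),
          run_duration_s = attr(run$events, "run_duration_s"),
          bold = paste0(file.path(sub, tms, rid), "_bold.nii.gz"))
      }
    }
  }
  readr::write_tsv(cohort$behavior, file.path(out_dir, "behavior.tsv"))
  brain <- array(TRUE, dim = cfg$grid_dims)
  write_mask_nifti(brain, cfg$voxel_size_mm,
                   file.path(out_dir, "masks", "brain.nii.gz"))
  for (rid in names(cfg$regions)) {
    m <- array(FALSE, dim = cfg$grid_dims)
    m[region_to_linear(cfg$regions[[rid]], cfg$grid_dims)] <- TRUE
    write_mask_nifti(m, cfg$voxel_size_mm,
                     file.path(out_dir, "masks", paste0(rid, ".nii.gz")))
  }
  manifest <- list(
    seed = cfg$seed,
    subject_seeds = cohort$subject_seeds,
    amp_scales = cohort$amp_scales,
    grid_dims = cfg$grid_dims,
    voxel_size_mm = cfg$voxel_size_mm,
    tr_s = cfg$tr_s,
    regions = lapply(cfg$regions, function(r) unname(as.data.frame(r))),
    disruption_factors = cfg$disruption_factors,
    runs = runs_index
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write / read a pattern set as a compressed tabular file with sidecar
#'
#' The trials x voxels matrix is written as gzipped TSV and the per-trial
#' labels, voxel coordinates (0-based in the sidecar, following the volume
#' convention of the NIfTI ecosystem), grid dims, and voxel size as a JSON
#' sidecar next to it.
#'
#' @param patterns A [pattern_set()].
#' @param path Path of the matrix file (e.g. `patterns.tsv.gz`); the sidecar
#'   is written as `<path>.json`.
#' @return `write_pattern_set` returns `path` invisibly; `read_pattern_set`
#'   returns a [pattern_set()].
#' @export
write_pattern_set <- function(patterns, path) {
  X <- as.data.frame(patterns$X)
  names(X) <- paste0("v", seq_len(ncol(X)))
  readr::write_tsv(X, path)
  sidecar <- list(
    info = patterns$info,
    coords0 = if (is.null(patterns$coords)) NULL else
      unname(as.data.frame(patterns$coords - 1L)),
    dims = patterns$dims,
    voxel_size_mm = patterns$voxel_size_mm
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  X <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  dimnames(X) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  coords <- NULL
  if (!is.null(side$coords0) && length(side$coords0)) {
    coords <- as.matrix(side$coords0) + 1L
    dimnames(coords) <- list(NULL, c("x", "y", "z"))
  }
  pattern_set(X, as_tibble(side$info), coords = coords, dims = side$dims,
              voxel_size_mm = side$voxel_size_mm %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort dataset directory back into memory
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `behavior`, `manifest`, `masks` (named list of
#'   logical arrays), and `subjects` (per subject, per session, a list of
#'   runs: `events`, `vol`, `motion`).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  behavior <- readr::read_tsv(file.path(dir, "behavior.tsv"),
                              show_col_types = FALSE)
  mask_files <- list.files(file.path(dir, "masks"), full.names = TRUE)
  masks <- lapply(mask_files, function(f) {
    img <- RNifti::readNifti(f)
    array(as.numeric(img) > 0.5, dim = dim(img))
  })
  names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(mask_files))
  subjects <- list()
  for (i in seq_len(nrow(manifest$runs))) {
    row <- manifest$runs[i, ]
    base <- sub("_bold\\.nii\\.gz$", "", file.path(dir, row$bold))
    ev <- readr::read_tsv(paste0(base, "_events.tsv"), show_col_types = FALSE)
    names(ev) <- c("onset_s", "duration_s", "category", "match", "correct")
    attr(ev, "condition") <- row$condition
    attr(ev, "run_id") <- row$run_id
    attr(ev, "tms_condition") <- row$tms_condition
    attr(ev, "run_duration_s") <- row$run_duration_s
    motion <- readr::read_tsv(paste0(base, "_motion.tsv"),
                              show_col_types = FALSE)
    run <- list(events = ev, vol = read_volume(paste0(base, "_bold.nii.gz")),
                motion = motion)
    subjects[[row$subject]][[row$tms_condition]][[row$run_id]] <- run
  }
  list(behavior = behavior, manifest = manifest, masks = masks,
       subjects = subjects)
}
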
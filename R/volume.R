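#' Construct a 4D BOLD volume
#'
#' A light container for an X x Y x Z x T grid of BOLD values with voxel
#' size, repetition time, and the acquisition time of the first volume.
#' Volume k (1-based) is treated as acquired starting at
#' `t0_s + (k - 1) * tr_s`.
#'
#' @param data 4D numeric array (all values finite).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param tr_s Repetition time in seconds.
#' @param t0_s Acquisition time of the first volume (s).
#' @return A `volume4d` object.
#' @export
volume4d <- function(data, voxel_size_mm, tr_s, t0_s = 0) {
  if (length(dim(data)) != 4) {
    abort("`data` must be a 4D array.", class = "boldmvpa_invalid_argument")
  }
  if (!all(is.finite(data))) {
    abort("`data` must be finite everywhere.", class = "boldmvpa_invalid_argument")
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 t0_s = t0_s),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d voxels x %d volumes, %.1f mm, TR %.2g s\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm, x$tr_s))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

n_volumes <- function(vol) dim(vol$data)[4]

# T x V matrix view (time by voxel) of a volume4d
as_time_by_voxel <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4]))
}

matrix_to_volume <- function(Y, template) {
  d <- dim(template$data)
  template$data <- array(t(Y), dim = d)
  template
}

#' Write / read a 4D volume as NIfTI-1
#'
#' @param vol A [volume4d()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume4d()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(rep(vol$voxel_size_mm, 3), vol$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume4d(array(as.numeric(img), dim = dim(img)), voxel_size_mm = pd[1],
           tr_s = if (length(pd) >= 4) pd[4] else 1)
}

write_mask_nifti <- function(mask_array, voxel_size_mm, path) {
  img <- RNifti::asNifti(array(as.numeric(mask_array), dim = dim(mask_array)))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a trial-pattern set
#'
#' Trials x voxels matrix together with per-trial labels and the voxel
#' coordinate registry; the substrate of all decoding functions.
#'
#' @param X Numeric matrix, trials x voxels.
#' @param info Data frame with one row per trial: columns `category`,
#'   `relevance`, `run_id`, `condition`, `tms_condition`.
#' @param coords Integer matrix (voxels x 3) of 1-based grid coordinates.
#' @param dims Integer vector of 3 grid dimensions.
#' @param voxel_size_mm Voxel size (mm).
#' @return A `pattern_set` object.
#' @export
pattern_set <- function(X, info, coords = NULL, dims = NULL,
                        voxel_size_mm = NA_real_) {
  info <- as_tibble(info)
  if (nrow(info) != nrow(X)) {
    abort("`info` must have one row per trial.", class = "boldmvpa_invalid_argument")
  }
  if (!is.null(coords) && nrow(coords) != ncol(X)) {
    abort("`coords` must have one row per voxel.", class = "boldmvpa_invalid_argument")
  }
  structure(list(X = X, info = info, coords = coords, dims = dims,
                 voxel_size_mm = voxel_size_mm),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d trials x %d voxels (%d runs)\n",
              nrow(x$X), ncol(x$X), length(unique(x$info$run_id))))
  invisible(x)
}

#' Pool pattern sets across runs
#'
#' @param sets List of [pattern_set()] objects sharing the same voxels.
#' @return A single [pattern_set()].
#' @export
bind_pattern_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  v <- vapply(sets, function(s) ncol(s$X), 1L)
  if (length(unique(v)) != 1) {
    abort("pattern sets have different voxel counts.",
          class = "boldmvpa_invalid_argument")
  }
  pattern_set(do.call(rbind, lapply(sets, function(s) s$X)),
              dplyr::bind_rows(lapply(sets, function(s) s$info)),
              coords = sets[[1]]$coords, dims = sets[[1]]$dims,
              voxel_size_mm = sets[[1]]$voxel_size_mm)
}

# labels of a pattern set for a given code, as 0/1 with 0 = the
# lexicographically smaller class
code_labels <- function(patterns, code = c("category", "relevance")) {
  code <- match.arg(code)
  lab <- patterns$info[[code]]
  lev <- sort(unique(lab))
  if (length(lev) != 2) {
    abort(sprintf("code '%s' does not take two values in this pattern set.", code),
          class = "boldmvpa_invalid_argument")
  }
  list(y = as.integer(lab == lev[2]), levels = lev)
}
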
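#' Construct an accuracy map
#'
#' A 3D grid of searchlight decoding accuracies with a valid-center mask;
#' values are `NaN` outside valid centers.
#'
#' @param values 3D numeric array.
#' @param valid Logical 3D array of valid centers.
#' @param cube_edge Searchlight edge length used.
#' @param code Decoded code name.
#' @param voxel_size_mm Voxel size (mm).
#' @return An `accuracy_map` object.
#' @export
accuracy_map <- function(values, valid, cube_edge, code,
                         voxel_size_mm = NA_real_) {
  values[!valid] <- NaN
  structure(list(values = values, valid = valid, cube_edge = cube_edge,
                 code = code, voxel_size_mm = voxel_size_mm),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<accuracy_map> %s code, edge %d, %dx%dx%d (%d valid centers), mean %.3f\n",
              x$code, x$cube_edge, d[1], d[2], d[3], sum(x$valid),
              mean(x$values[x$valid])))
  invisible(x)
}

#' Write an accuracy map as NIfTI (NaN outside valid centers)
#'
#' @param map An [accuracy_map()].
#' @param path Output path.
#' @export
write_accuracy_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  if (!is.na(map$voxel_size_mm)) {
    RNifti::pixdim(img) <- rep(map$voxel_size_mm, 3)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gaussian Naive Bayes cubic searchlight accuracy map
#'
#' Moves a cube of `cube_edge` voxels across every in-mask center; features
#' are the in-mask voxels inside the (border-clipped) cube; a GNB classifier
#' is cross-validated with the run-pair scheme and the unweighted mean fold
#' accuracy is assigned to the center voxel. Centers whose clipped cube
#' contains fewer than `cube_edge^3 / 2` in-mask voxels are marked invalid
#' (`NaN`).
#'
#' @param patterns A [pattern_set()] carrying voxel coordinates and grid
#'   dims (the in-mask voxels are the pattern-set voxels).
#' @param code Label to decode (`"category"` or `"relevance"`).
#' @param cv Optional `cv_scheme`; defaults to sorted run-pair folds.
#' @param cube_edge Odd cube edge (3 -> 27-voxel searchlight, 5 -> 125).
#' @param var_floor Pooled-variance floor.
#' @return An [accuracy_map()].
#' @export
searchlight_accuracy_map <- function(patterns, code = c("category", "relevance"),
                                     cv = NULL, cube_edge = 3,
                                     var_floor = 1e-6) {
  code <- match.arg(code)
  lab <- code_labels(patterns, code)
  res <- searchlight_batch(patterns, matrix(lab$y, ncol = 1), cv, cube_edge,
                           var_floor)
  accuracy_map(res$maps[[1]], res$valid_arr, cube_edge, code,
               patterns$voxel_size_mm)
}

# batched searchlight over a matrix of 0/1 label vectors; returns list of
# 3D arrays plus validity
searchlight_batch <- function(patterns, label_matrix, cv = NULL, cube_edge = 3,
                              var_floor = 1e-6) {
  if (cube_edge %% 2 != 1) {
    abort("`cube_edge` must be odd.", class = "boldmvpa_invalid_argument")
  }
  if (is.null(patterns$coords) || is.null(patterns$dims)) {
    abort("pattern set lacks voxel coordinates / grid dims.",
          class = "boldmvpa_invalid_argument")
  }
  if (is.null(cv)) {
    cv <- make_run_pair_folds(dplyr::distinct(patterns$info, .data$run_id,
                                              .data$condition))
  }
  fold <- trial_folds(patterns, cv)
  n_folds <- attr(cv, "n_folds")
  dims <- patterns$dims
  vox0 <- region_to_linear(patterns$coords, dims) - 1L
  res <- cpp_searchlight(patterns$X, vox0, dims, fold, n_folds,
                         label_matrix, as.integer(cube_edge), var_floor)
  valid_arr <- array(FALSE, dim = dims)
  valid_arr[vox0 + 1L] <- res$valid
  maps <- lapply(seq_len(ncol(label_matrix)), function(s) {
    m <- array(NaN, dim = dims)
    m[vox0 + 1L] <- res$acc[, s]
    m
  })
  list(maps = maps, valid_arr = valid_arr, nfeat = res$nfeat,
       prop_floored = res$prop_floored)
}

#' @rdname searchlight_accuracy_map
#' @param x An `accuracy_map`.
#' @param ... Unused.
#' @method tidy accuracy_map
#' @export
tidy.accuracy_map <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  vals <- x$values[x$valid]
  tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3], accuracy = vals)
}

#' Plot an axial slice of an accuracy map
#'
#' @param object An [accuracy_map()].
#' @param slice_z Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_map
#' @export
autoplot.accuracy_map <- function(object, slice_z = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice_z)) slice_z <- ceiling(d[3] / 2)
  df <- tidy(object)
  df <- df[df$z == slice_z, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s code searchlight (edge %d), z = %d",
                                  object$code, object$cube_edge, slice_z),
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}
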
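#' Masked Gaussian smoothing of a 3D map
#'
#' Separable Gaussian smoothing with sigma = FWHM / (2 sqrt(2 ln 2)) /
#' voxel size per axis. Non-finite cells (e.g. invalid searchlight centers)
#' are excluded by normalized masked convolution: both `map * valid` and
#' `valid` are smoothed and their ratio returned, so a constant map stays
#' constant and no mass leaks from the invalid region. `fwhm_mm = 0` is the
#' identity. The kernel is truncated at 4 sigma.
#'
#' @param map 3D numeric array (may contain `NaN`/`NA`).
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @param voxel_size_mm Voxel size in mm.
#' @return Smoothed 3D array; cells that were non-finite stay `NaN`.
#' @export
smooth_gaussian <- function(map, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) {
    abort("`fwhm_mm` must be >= 0.", class = "boldmvpa_invalid_argument")
  }
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-0.5 * ((-r):r / sigma)^2)
  kern <- kern / sum(kern)

  valid <- is.finite(map)
  num <- map
  num[!valid] <- 0
  den <- array(as.numeric(valid), dim = dim(map))
  for (axis in 1:3) {
    num <- convolve_axis(num, kern, axis)
    den <- convolve_axis(den, kern, axis)
  }
  out <- array(NaN, dim = dim(map))
  ok <- valid & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# 1-D convolution of a 3D array along one axis with zero padding
convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  r <- (length(kern) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (j in seq_along(kern)) {
    off <- j - r - 1L
    w <- kern[j]
    if (w == 0) next
    src <- shift_axis(arr, -off, axis)
    out <- out + w * src
  }
  out
}

# shift a 3D array by `by` cells along `axis`, zero-filling
shift_axis <- function(arr, by, axis) {
  if (by == 0) return(arr)
  d <- dim(arr)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  idx_to <- if (by > 0) (by + 1):n else 1:(n + by)
  idx_from <- if (by > 0) 1:(n - by) else (1 - by):n
  ix <- function(i) switch(axis,
                           list(i, TRUE, TRUE),
                           list(TRUE, i, TRUE),
                           list(TRUE, TRUE, i))
  a <- ix(idx_to); b <- ix(idx_from)
  out[a[[1]], a[[2]], a[[3]]] <- arr[b[[1]], b[[2]], b[[3]]]
  out
}

#' Dilate a binary 3D mask
#'
#' Face-connected (6-neighbour) dilation repeated `r` times.
#'
#' @param mask Logical 3D array.
#' @param r Number of dilation steps.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, r = 1) {
  out <- mask
  for (i in seq_len(r)) {
    grown <- out
    for (axis in 1:3) {
      grown <- grown | (shift_axis(array(as.numeric(out), dim(out)), 1, axis) > 0)
      grown <- grown | (shift_axis(array(as.numeric(out), dim(out)), -1, axis) > 0)
    }
    out <- grown
  }
  out
}
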
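#' Extract face-connected clusters from a binary map
#'
#' Connected components under 6-connectivity (voxels sharing faces, not
#' edges or corners).
#'
#' @param binary_map Logical 3D array.
#' @return A `cluster_report`: tibble with one row per cluster (`cluster`,
#'   `size`, `com_x`, `com_y`, `com_z`, `survives` -- `NA` until a cluster
#'   threshold is applied) and attributes `labels` (integer 3D array) and
#'   `dims`.
#' @export
extract_clusters <- function(binary_map) {
  d <- dim(binary_map)
  res <- cpp_label_clusters(as.integer(binary_map), as.integer(d))
  labels <- array(res$labels, dim = d)
  n <- length(res$sizes)
  if (n == 0) {
    rep_tbl <- tibble(cluster = integer(), size = integer(),
                      com_x = numeric(), com_y = numeric(),
                      com_z = numeric(), survives = logical())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    com <- vapply(seq_len(n), function(k) {
      unname(colMeans(idx[lab == k, , drop = FALSE]))
    }, numeric(3))
    rep_tbl <- tibble(cluster = seq_len(n), size = as.integer(res$sizes),
                      com_x = com[1, ], com_y = com[2, ], com_z = com[3, ],
                      survives = NA)
  }
  structure(rep_tbl, labels = labels, dims = d,
            class = c("cluster_report", class(rep_tbl)))
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d face-connected clusters\n", nrow(x)))
  NextMethod()
}
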
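# Independent brute-force oracles used to validate the optimized
# implementations on small instances.

# GNB by direct evaluation of full Gaussian densities per class
oracle_gnb <- function(train_x, train_labels, test_x, var_floor = 1e-6) {
  lev <- sort(unique(as.character(train_labels)))
  n <- nrow(train_x)
  m <- list(); ss <- list()
  for (l in lev) {
    xs <- train_x[train_labels == l, , drop = FALSE]
    m[[l]] <- colMeans(xs)
    ss[[l]] <- colSums(sweep(xs, 2, colMeans(xs))^2)
  }
  v <- (ss[[1]] + ss[[2]]) / (n - 2)
  v <- pmax(v, var_floor)
  prior <- table(factor(train_labels, levels = lev)) / n
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ll <- vapply(lev, function(l) {
      sum(stats::dnorm(test_x[i, ], m[[l]], sqrt(v), log = TRUE)) +
        log(prior[[l]])
    }, 1)
    pred[i] <- if (ll[2] > ll[1]) lev[2] else lev[1]
  }
  pred
}

# empirical p by explicit counting
oracle_empirical_p <- function(null, observed) {
  sum(null > observed) / length(null)
}

# 6-connectivity components by breadth-first search in plain R
oracle_clusters <- function(binary_map) {
  d <- dim(binary_map)
  lab <- array(0L, dim = d)
  k <- 0L
  sizes <- integer(0)
  idx_all <- which(binary_map)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    sz <- 0L
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      sz <- sz + 1L
      co <- arrayInd(cur, d)
      for (axis in 1:3) {
        for (step in c(-1L, 1L)) {
          nb <- co
          nb[axis] <- nb[axis] + step
          if (nb[axis] < 1 || nb[axis] > d[axis]) next
          lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
          if (binary_map[lin] && lab[lin] == 0L) {
            lab[lin] <- k
            queue <- c(queue, lin)
          }
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = lab, sizes = sizes)
}

# Welch t from the closed-form formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Spearman rho / exact two-sided permutation p by direct enumeration,
# computing rho with cor() on explicitly permuted rank vectors
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- gtools_permutations(length(y))
  rho_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
  list(rho = rho, p = mean(abs(rho_all) >= abs(rho) - 1e-12))
}

# iterative (non-recursive) permutation generator, distinct from the
# package's recursive one
gtools_permutations <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    new <- matrix(0L, nrow(out) * m, m)
    r <- 0L
    for (i in seq_len(nrow(out))) {
      for (pos in seq_len(m)) {
        row <- append(out[i, ], m, after = pos - 1L)
        r <- r + 1L
        new[r, ] <- row
      }
    }
    out <- new
  }
  out
}

# brute-force searchlight: per center, gather in-mask cube voxels and run
# gnb_fit_predict fold by fold
oracle_searchlight <- function(patterns, code, cube_edge, cv) {
  dims <- patterns$dims
  r <- (cube_edge - 1) / 2
  lab <- patterns$info[[code]]
  fold <- boldmvpa:::trial_folds(patterns, cv)
  have <- boldmvpa:::region_to_linear(patterns$coords, dims)
  out <- array(NaN, dim = dims)
  valid <- array(FALSE, dim = dims)
  for (v in seq_len(nrow(patterns$coords))) {
    cc <- patterns$coords[v, ]
    xs <- max(cc[1] - r, 1):min(cc[1] + r, dims[1])
    ys <- max(cc[2] - r, 1):min(cc[2] + r, dims[2])
    zs <- max(cc[3] - r, 1):min(cc[3] + r, dims[3])
    cube <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    cols <- match(boldmvpa:::region_to_linear(cube, dims), have)
    cols <- cols[!is.na(cols)]
    if (length(cols) < cube_edge^3 / 2) next
    valid[cc[1], cc[2], cc[3]] <- TRUE
    accs <- vapply(sort(unique(fold)), function(f) {
      pred <- gnb_fit_predict(patterns$X[fold != f, cols, drop = FALSE],
                              lab[fold != f],
                              patterns$X[fold == f, cols, drop = FALSE])
      mean(pred == lab[fold == f])
    }, 1)
    out[cc[1], cc[2], cc[3]] <- mean(accs)
  }
  list(values = out, valid = valid)
}
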
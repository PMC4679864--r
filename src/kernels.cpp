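// Compiled kernels for the permutation/bootstrap-heavy inner loops:
//  - L2-penalized logistic regression under run-pair CV, batched over
//    permutation label sets (the ROI decoding + null-distribution engine);
//  - Gaussian Naive Bayes cubic searchlight, batched over label sets.
//    The binary pooled-variance GNB decision rule is linear in the voxel
//    values, so per-center cube sums are computed with 3-D prefix sums
//    (a box filter); this is algebraically identical to fitting GNB
//    independently in every searchlight.
//  - Face-connected (6-neighbour) component labelling for cluster-extent
//    inference.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Penalized negative log-likelihood: -sum[y*log p + (1-y)*log(1-p)] +
// lambda/2 * ||w||^2 (intercept unpenalized).
static double pen_nll(const arma::vec& eta, const arma::vec& y,
                      const arma::vec& beta, double lambda) {
  double nll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    // log(1 + exp(e)) - y*e, computed stably
    double l1pe = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    nll += l1pe - y[i] * e;
  }
  double pen = 0.0;
  for (arma::uword j = 1; j < beta.n_elem; ++j) pen += beta[j] * beta[j];
  return nll + 0.5 * lambda * pen;
}

// Fit one L2-logistic model by Newton iterations with step halving,
// starting from beta (warm start allowed). Sets converged / n_iter.
static void fit_logreg(const arma::mat& Xa, const arma::vec& y, double lambda,
                       double tol, int maxit, arma::vec& beta, bool& converged,
                       int& n_iter) {
  const arma::uword p1 = Xa.n_cols;
  arma::vec eta = Xa * beta;
  double f = pen_nll(eta, y, beta, lambda);
  converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    arma::vec prob(eta.n_elem), w(eta.n_elem);
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      double pi = sigmoid(eta[i]);
      prob[i] = pi;
      double wi = pi * (1.0 - pi);
      w[i] = (wi < 1e-10) ? 1e-10 : wi;
    }
    arma::vec g = Xa.t() * (prob - y);
    for (arma::uword j = 1; j < p1; ++j) g[j] += lambda * beta[j];
    if (arma::norm(g, 2) < tol) { converged = true; break; }
    arma::mat H = Xa.t() * (Xa.each_col() % w);
    for (arma::uword j = 1; j < p1; ++j) H(j, j) += lambda;
    arma::vec step;
    bool ok = arma::solve(step, H, g, arma::solve_opts::likely_sympd);
    if (!ok) { arma::solve(step, H, g); }
    // step halving on the penalized objective
    double t = 1.0;
    for (int h = 0; h < 30; ++h) {
      arma::vec beta_new = beta - t * step;
      arma::vec eta_new = Xa * beta_new;
      double f_new = pen_nll(eta_new, y, beta_new, lambda);
      if (f_new <= f + 1e-12) {
        beta = beta_new; eta = eta_new; f = f_new;
        break;
      }
      t *= 0.5;
    }
  }
  n_iter = it;
}

// Cross-validated accuracy of L2 logistic regression for each label set.
// X: n x p pattern matrix; labels: n x S integer 0/1 matrix; fold: length-n
// vector giving each trial's *test* fold (1..nfold). Returns S x nfold
// accuracies plus convergence bookkeeping.
// [[Rcpp::export]]
List cpp_logreg_cv(const arma::mat& X, const arma::imat& labels,
                   const arma::ivec& fold, int nfold, double lambda,
                   double tol, int maxit) {
  const arma::uword n = X.n_rows;
  const int S = labels.n_cols;
  arma::mat Xa(n, X.n_cols + 1);
  Xa.col(0).ones();
  Xa.cols(1, X.n_cols) = X;

  std::vector<std::vector<arma::uword>> test_idx(nfold), train_idx(nfold);
  for (arma::uword i = 0; i < n; ++i) {
    int f = fold[i] - 1;
    for (int g = 0; g < nfold; ++g)
      (g == f ? test_idx[g] : train_idx[g]).push_back(i);
  }

  arma::mat acc(S, nfold);
  LogicalMatrix conv(S, nfold);
  IntegerMatrix iters(S, nfold);
  for (int f = 0; f < nfold; ++f) {
    arma::uvec tr(train_idx[f]), te(test_idx[f]);
    arma::mat Xtr = Xa.rows(tr), Xte = Xa.rows(te);
    arma::vec beta0(Xa.n_cols, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      arma::vec y(tr.n_elem);
      for (arma::uword i = 0; i < tr.n_elem; ++i) y[i] = labels(tr[i], s);
      bool cv_ok; int nit;
      // warm start from the previous label set's solution (convex problem,
      // purely a speed device)
      arma::vec beta = beta0;
      fit_logreg(Xtr, y, lambda, tol, maxit, beta, cv_ok, nit);
      if (s == 0) beta0 = beta;
      conv(s, f) = cv_ok;
      iters(s, f) = nit;
      arma::vec eta = Xte * beta;
      int correct = 0;
      for (arma::uword i = 0; i < te.n_elem; ++i) {
        int pred = (sigmoid(eta[i]) > 0.5) ? 1 : 0;
        if (pred == labels(te[i], s)) ++correct;
      }
      acc(s, f) = static_cast<double>(correct) / te.n_elem;
    }
  }
  return List::create(_["acc"] = acc, _["converged"] = conv,
                      _["iterations"] = iters);
}

// ---- searchlight ----------------------------------------------------------

// In-place 3-D inclusive prefix sum over a padded grid with dims
// (nx+1, ny+1, nz+1), x fastest; the first layer along each axis is zero.
static void prefix3d(double* P, int nx, int ny, int nz) {
  const int px = nx + 1, py = ny + 1;
  const size_t slab = (size_t)px * py;
  for (int k = 1; k <= nz; ++k) {
    double* Pk = P + (size_t)k * slab;
    const double* Pk1 = Pk - slab;
    for (int j = 1; j <= ny; ++j) {
      double* row = Pk + (size_t)j * px;
      const double* row_up = row - px;
      const double* prev = Pk1 + (size_t)j * px;
      const double* prev_up = prev - px;
      double run = 0.0; // running x-sum of the current (j,k) row of A
      for (int i = 1; i <= nx; ++i) {
        run += row[i];
        row[i] = run + row_up[i] + prev[i] - prev_up[i];
      }
    }
  }
}

// GNB cubic searchlight, batched over label sets.
// X: n x V (V in-mask voxels); vox: V 0-based linear grid indices
// (x fastest); dims: (nx, ny, nz); fold: test fold per trial (1..nfold);
// labels: n x S 0/1; edge: odd cube edge; var_floor: pooled-variance floor.
// Returns V x S accuracy (NaN at invalid centers), validity, feature counts,
// and the fraction of floored variances.
// [[Rcpp::export]]
List cpp_searchlight(const arma::mat& X, const arma::ivec& vox,
                     const arma::ivec& dims, const arma::ivec& fold,
                     int nfold, const arma::imat& labels, int edge,
                     double var_floor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword n = X.n_rows, V = X.n_cols;
  const int S = labels.n_cols;
  const int r = (edge - 1) / 2;
  const double cube_vol = (double)edge * edge * edge;
  const int px = nx + 1, py = ny + 1;
  const size_t PN = (size_t)px * py * (nz + 1);

  // voxel coordinates, padded-grid index, and the 8 prefix corners per box
  std::vector<int> cx(V), cy(V), cz(V);
  std::vector<size_t> pidx(V);
  auto pat = [&](int i, int j, int k) -> size_t {
    return (size_t)k * px * py + (size_t)j * px + i;
  };
  for (arma::uword v = 0; v < V; ++v) {
    long g = vox[v];
    cx[v] = g % nx; cy[v] = (g / nx) % ny; cz[v] = g / ((long)nx * ny);
    pidx[v] = pat(cx[v] + 1, cy[v] + 1, cz[v] + 1);
  }
  // mask prefix for occupancy counts
  std::vector<double> Pm(PN, 0.0);
  for (arma::uword v = 0; v < V; ++v) Pm[pidx[v]] = 1.0;
  prefix3d(Pm.data(), nx, ny, nz);

  // 8 corner offsets (sign, padded index) per center for box sums
  std::vector<std::array<size_t, 8>> corner(V);
  // corner signs: +(x1,y1,z1) -(x0,y1,z1) -(x1,y0,z1) -(x1,y1,z0)
  //               +(x0,y0,z1) +(x0,y1,z0) +(x1,y0,z0) -(x0,y0,z0)
  IntegerVector nfeat(V);
  LogicalVector valid(V);
  for (arma::uword v = 0; v < V; ++v) {
    int x0 = std::max(cx[v] - r, 0), x1 = std::min(cx[v] + r, nx - 1);
    int y0 = std::max(cy[v] - r, 0), y1 = std::min(cy[v] + r, ny - 1);
    int z0 = std::max(cz[v] - r, 0), z1 = std::min(cz[v] + r, nz - 1);
    corner[v] = {pat(x1 + 1, y1 + 1, z1 + 1), pat(x0, y1 + 1, z1 + 1),
                 pat(x1 + 1, y0, z1 + 1),     pat(x1 + 1, y1 + 1, z0),
                 pat(x0, y0, z1 + 1),         pat(x0, y1 + 1, z0),
                 pat(x1 + 1, y0, z0),         pat(x0, y0, z0)};
    double m = Pm[corner[v][0]] - Pm[corner[v][1]] - Pm[corner[v][2]]
             - Pm[corner[v][3]] + Pm[corner[v][4]] + Pm[corner[v][5]]
             + Pm[corner[v][6]] - Pm[corner[v][7]];
    nfeat[v] = (int)std::lround(m);
    valid[v] = (m >= cube_vol / 2.0);
  }
  auto box = [&](const double* P, arma::uword v) -> double {
    const std::array<size_t, 8>& c = corner[v];
    return P[c[0]] - P[c[1]] - P[c[2]] - P[c[3]] + P[c[4]] + P[c[5]] + P[c[6]]
         - P[c[7]];
  };

  std::vector<std::vector<arma::uword>> test_idx(nfold);
  for (arma::uword i = 0; i < n; ++i) test_idx[fold[i] - 1].push_back(i);

  // transposed data (V x n) for sequential per-voxel accumulation
  arma::mat Xt = X.t();
  arma::mat Xt2 = arma::square(Xt);

  arma::mat acc(V, S, arma::fill::zeros);
  long floored = 0, var_cells = 0;
  std::vector<double> PB(PN), PC(PN), boxB(V), w(V), b(V);
  arma::mat fold_acc(V, nfold);

  for (int s = 0; s < S; ++s) {
    // per-(fold, class) trial lists
    std::vector<std::vector<arma::uword>> members(nfold * 2);
    arma::imat cnt(nfold, 2, arma::fill::zeros);
    arma::ivec tot(2, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      int f = fold[i] - 1, c = labels(i, s);
      members[f * 2 + c].push_back(i);
      cnt(f, c)++; tot[c]++;
    }
    // per-voxel sums and sums of squares per (fold, class), plus totals
    arma::mat Ssum(V, nfold * 2, arma::fill::zeros);
    arma::mat Qsum(V, nfold * 2, arma::fill::zeros);
    for (int fc = 0; fc < nfold * 2; ++fc) {
      for (arma::uword t : members[fc]) {
        Ssum.col(fc) += Xt.col(t);
        Qsum.col(fc) += Xt2.col(t);
      }
    }
    arma::mat TsumM(V, 2, arma::fill::zeros), TQM(V, 2, arma::fill::zeros);
    for (int f = 0; f < nfold; ++f)
      for (int c = 0; c < 2; ++c) {
        TsumM.col(c) += Ssum.col(f * 2 + c);
        TQM.col(c) += Qsum.col(f * 2 + c);
      }

    for (int f = 0; f < nfold; ++f) {
      long n0 = tot[0] - cnt(f, 0), n1 = tot[1] - cnt(f, 1);
      if (n0 < 2 || n1 < 2)
        stop("searchlight: a training fold has fewer than 2 trials in a class");
      double logprior = std::log((double)n1 / (double)n0);
      const double* S0 = Ssum.colptr(f * 2 + 0);
      const double* S1 = Ssum.colptr(f * 2 + 1);
      const double* Q0 = Qsum.colptr(f * 2 + 0);
      const double* Q1 = Qsum.colptr(f * 2 + 1);
      const double* T0 = TsumM.colptr(0);
      const double* T1 = TsumM.colptr(1);
      const double* U0 = TQM.colptr(0);
      const double* U1 = TQM.colptr(1);
      for (arma::uword v = 0; v < V; ++v) {
        double s0 = T0[v] - S0[v], s1 = T1[v] - S1[v];
        double q0 = U0[v] - Q0[v], q1 = U1[v] - Q1[v];
        double m0 = s0 / n0, m1 = s1 / n1;
        double ssw = (q0 - n0 * m0 * m0) + (q1 - n1 * m1 * m1);
        double var = ssw / (double)(n0 + n1 - 2);
        ++var_cells;
        if (var < var_floor) { var = var_floor; ++floored; }
        w[v] = (m1 - m0) / var;
        b[v] = (m0 * m0 - m1 * m1) / (2.0 * var);
      }
      // bias-term box sums (trial independent)
      std::fill(PB.begin(), PB.end(), 0.0);
      for (arma::uword v = 0; v < V; ++v) PB[pidx[v]] = b[v];
      prefix3d(PB.data(), nx, ny, nz);
      for (arma::uword v = 0; v < V; ++v) boxB[v] = box(PB.data(), v);

      const std::vector<arma::uword>& te = test_idx[f];
      std::vector<int> correct(V, 0);
      for (arma::uword t : te) {
        int yt = labels(t, s);
        const double* xt = Xt.colptr(t);
        std::fill(PC.begin(), PC.end(), 0.0);
        for (arma::uword v = 0; v < V; ++v) PC[pidx[v]] = w[v] * xt[v];
        prefix3d(PC.data(), nx, ny, nz);
        const double* P = PC.data();
        for (arma::uword v = 0; v < V; ++v) {
          double score = box(P, v) + boxB[v] + logprior;
          int pred = (score > 0) ? 1 : 0; // tie -> lexicographically smaller
          correct[v] += (pred == yt);
        }
      }
      double inv_te = 1.0 / (double)te.size();
      for (arma::uword v = 0; v < V; ++v)
        fold_acc(v, f) = correct[v] * inv_te;
    }
    for (arma::uword v = 0; v < V; ++v)
      acc(v, s) = valid[v] ? arma::mean(fold_acc.row(v)) : NA_REAL;
  }
  return List::create(_["acc"] = acc, _["valid"] = valid, _["nfeat"] = nfeat,
                      _["prop_floored"] =
                        var_cells ? (double)floored / var_cells : 0.0);
}

// ---- clustering -----------------------------------------------------------

static int label_components(const int* bin, int nx, int ny, int nz,
                            std::vector<int>& lab, std::vector<int>& sizes) {
  const size_t NG = (size_t)nx * ny * nz;
  std::fill(lab.begin(), lab.end(), 0);
  sizes.clear();
  std::vector<size_t> stack;
  int k = 0;
  for (size_t g = 0; g < NG; ++g) {
    if (!bin[g] || lab[g]) continue;
    ++k;
    int sz = 0;
    stack.push_back(g);
    lab[g] = k;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      ++sz;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t gg = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (bin[gg] && !lab[gg]) { lab[gg] = k; stack.push_back(gg); }
      }
    }
    sizes.push_back(sz);
  }
  return k;
}

// Face-connected component labels of a binary 3-D grid (x fastest).
// [[Rcpp::export]]
List cpp_label_clusters(const IntegerVector& bin, const IntegerVector& dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab((size_t)nx * ny * nz), sizes;
  label_components(&bin[0], nx, ny, nz, lab, sizes);
  return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Maximum face-connected cluster size in each column of a stack of binary
// maps (grid cells x maps).
// [[Rcpp::export]]
IntegerVector cpp_max_cluster_sizes(const IntegerMatrix& binmaps,
                                    const IntegerVector& dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = binmaps.ncol();
  IntegerVector out(M);
  std::vector<int> lab((size_t)nx * ny * nz), sizes;
  for (int m = 0; m < M; ++m) {
    label_components(&binmaps(0, m), nx, ny, nz, lab, sizes);
    int mx = 0;
    for (int s : sizes) mx = std::max(mx, s);
    out[m] = mx;
  }
  return out;
}
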
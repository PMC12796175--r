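// Pixel-wise empirical p-values, connected-component labelling and the
// permutation null of maximum cluster sizes.  Grids are passed flattened
// (column-major, as R stores matrices); the cohort is an n x 4096 matrix
// with one registered valid map per row.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Two-tailed empirical p-value with add-one correction, ties counted on
// both tails: p = min(1, 2 * min(p_high, p_low)),
// p_high = (1 + #{x >= t}) / (n + 1), p_low = (1 + #{x <= t}) / (n + 1).
static inline double pval_one(double t, const double* x, int n, int skip) {
  int ge = 0, le = 0;
  for (int i = 0; i < n; ++i) {
    if (i == skip) continue;
    if (x[i] >= t) ++ge;
    if (x[i] <= t) ++le;
  }
  int m = (skip >= 0) ? n - 1 : n;
  double ph = (1.0 + ge) / (m + 1.0);
  double pl = (1.0 + le) / (m + 1.0);
  double p = 2.0 * std::min(ph, pl);
  return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export(name = ".pmap_cpp")]]
NumericVector pmap_cpp(NumericVector test, const arma::mat& cohort) {
  const int npix = test.size();
  const int n = cohort.n_rows;
  NumericVector out(npix);
  for (int j = 0; j < npix; ++j) {
    arma::vec col = cohort.col(j);
    out[j] = pval_one(test[j], col.memptr(), n, -1);
  }
  return out;
}

// Label connected components of a logical mask under 4- or 8-connectivity.
// Returns an integer matrix of labels (0 = background, 1..k = components).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qr(H * W), qc(H * W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = r; qc[tail] = c; ++tail;
      lab(r, c) = next;
      while (head < tail) {
        int cr = qr[head], cc = qc[head]; ++head;
        for (int k = 0; k < nd; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            qr[tail] = nr; qc[tail] = nc; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

static int max_surviving_cluster(const std::vector<double>& p, int H, int W,
                                 double alpha, int min_cluster, int connectivity) {
  LogicalMatrix mask(H, W);
  bool any = false;
  for (int j = 0; j < H * W; ++j) {
    bool s = p[j] < alpha;
    mask[j] = s;
    any = any || s;
  }
  if (!any) return 0;
  IntegerMatrix lab = label_components_cpp(mask, connectivity);
  int k = 0;
  for (int j = 0; j < H * W; ++j) k = std::max(k, lab[j]);
  std::vector<int> sz(k + 1, 0);
  for (int j = 0; j < H * W; ++j) ++sz[lab[j]];
  int best = 0;
  for (int i = 1; i <= k; ++i)
    if (sz[i] >= min_cluster && sz[i] > best) best = sz[i];
  return best;
}

// Permutation null of maximum surviving cluster sizes: each iteration draws
// one cohort member (uniformly, with replacement across iterations), scores
// it against the remaining n-1 members (leave-one-out), and records the
// largest cluster passing the forming threshold and minimum-size filter.
// [[Rcpp::export(name = ".null_max_sizes_cpp")]]
IntegerVector null_max_sizes_cpp(const arma::mat& cohort, int H, int W,
                                 double alpha_forming, int min_cluster,
                                 int connectivity, int n_perm, int seed) {
  const int n = cohort.n_rows, npix = H * W;
  std::mt19937 rng((uint32_t)seed);
  IntegerVector out(n_perm);
  std::vector<double> p(npix);
  for (int it = 0; it < n_perm; ++it) {
    int idx = (int)(rng() % (uint32_t)n);
    for (int j = 0; j < npix; ++j) {
      arma::vec col = cohort.col(j);
      p[j] = pval_one(cohort(idx, j), col.memptr(), n, idx);
    }
    out[it] = max_surviving_cluster(p, H, W, alpha_forming, min_cluster, connectivity);
  }
  return out;
}
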
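#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Prototype matrices cross the R boundary as nodes x dim; internally each
// node's vector is kept contiguous (row-major) for cache-friendly scans.

static std::vector<double> to_row_major(const NumericMatrix& M) {
  int n = M.nrow(), d = M.ncol();
  std::vector<double> v((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      v[(size_t)i * d + j] = M(i, j);
  return v;
}

static NumericMatrix from_row_major(const std::vector<double>& v, int n, int d) {
  NumericMatrix M(n, d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      M(i, j) = v[(size_t)i * d + j];
  return M;
}

// Best-matching unit: node minimising squared Euclidean distance to x.
// Strict '<' while scanning in row-major node order implements the
// smallest-linear-index tie-break; early exit cannot select a tied later
// node because its partial sum reaches 'best' and breaks without winning.
static int bmu_of(const std::vector<double>& W, int nodes, int dim,
                  const double* x, double* dist2_out) {
  double best = R_PosInf;
  int bi = 0;
  for (int k = 0; k < nodes; ++k) {
    const double* w = &W[(size_t)k * dim];
    double s = 0.0;
    for (int j = 0; j < dim; ++j) {
      double diff = x[j] - w[j];
      s += diff * diff;
      if (s >= best) break;
    }
    if (s < best) { best = s; bi = k; }
  }
  if (dist2_out) *dist2_out = best;
  return bi;
}

// Deterministic Fisher-Yates; std::shuffle is implementation-defined, the
// raw mt19937 stream is not.
static void fy_shuffle(std::vector<int>& idx, std::mt19937& gen) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)(gen() % (uint32_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_bmu_batch(NumericMatrix W, NumericMatrix X) {
  int nodes = W.nrow(), dim = W.ncol(), n = X.nrow();
  if (X.ncol() != dim) stop("dimension mismatch: map dim %d, data dim %d", dim, X.ncol());
  std::vector<double> Wv = to_row_major(W), Xv = to_row_major(X);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = bmu_of(Wv, nodes, dim, &Xv[(size_t)i * dim], nullptr);
  return out;  // 0-based linear (row-major) node indices
}

// [[Rcpp::export]]
NumericVector cpp_bmu_dist(NumericMatrix W, NumericMatrix X) {
  int nodes = W.nrow(), dim = W.ncol(), n = X.nrow();
  if (X.ncol() != dim) stop("dimension mismatch: map dim %d, data dim %d", dim, X.ncol());
  std::vector<double> Wv = to_row_major(W), Xv = to_row_major(X);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    bmu_of(Wv, nodes, dim, &Xv[(size_t)i * dim], &d2);
    out[i] = std::sqrt(d2);
  }
  return out;
}

// Online Kohonen training. lr/radius give the per-epoch schedule. coords are
// the integer grid coordinates of each node; kernel 0 = gaussian, 1 = bubble.
// Updates with neighbourhood weight below h_cutoff are skipped. The per-epoch
// quantization error is the online one: each case's distance to its BMU at
// presentation time, averaged over the epoch.
// [[Rcpp::export]]
List cpp_train_sofm(NumericMatrix W, NumericMatrix X,
                    NumericVector lr, NumericVector radius,
                    NumericMatrix coords, int kernel,
                    int seed, double h_cutoff) {
  int nodes = W.nrow(), dim = W.ncol(), n = X.nrow();
  int epochs = lr.size();
  if (radius.size() != epochs) stop("lr and radius schedules differ in length");
  std::vector<double> Wv = to_row_major(W), Xv = to_row_major(X);

  // pairwise squared grid distances between nodes
  std::vector<double> d2((size_t)nodes * nodes);
  for (int a = 0; a < nodes; ++a)
    for (int b = 0; b < nodes; ++b) {
      double dr = coords(a, 0) - coords(b, 0), dc = coords(a, 1) - coords(b, 1);
      d2[(size_t)a * nodes + b] = dr * dr + dc * dc;
    }

  std::mt19937 gen((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector qe(epochs);
  std::vector<double> H((size_t)nodes * nodes);

  for (int e = 0; e < epochs; ++e) {
    double r = radius[e], a = lr[e];
    double denom = 2.0 * r * r;
    for (size_t p = 0; p < H.size(); ++p)
      H[p] = (kernel == 0) ? std::exp(-d2[p] / denom)
                           : (d2[p] <= r * r ? 1.0 : 0.0);
    fy_shuffle(order, gen);
    double qsum = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      const double* x = &Xv[(size_t)order[ii] * dim];
      double bd2;
      int b = bmu_of(Wv, nodes, dim, x, &bd2);
      qsum += std::sqrt(bd2);
      const double* hrow = &H[(size_t)b * nodes];
      for (int k = 0; k < nodes; ++k) {
        double h = hrow[k];
        if (h < h_cutoff) continue;
        double ah = a * h;
        double* w = &Wv[(size_t)k * dim];
        for (int j = 0; j < dim; ++j) w[j] += ah * (x[j] - w[j]);
      }
    }
    qe[e] = qsum / n;
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["prototypes"] = from_row_major(Wv, nodes, dim),
                      _["qe"] = qe);
}

// LVQ1: only the BMU moves, towards a same-class case and away from a
// different-class one. Node labels are fixed. After each epoch the validation
// quality (fraction of validation cases whose BMU label matches) is computed;
// the prototypes with the best validation quality are returned (ties keep the
// earliest epoch).
// [[Rcpp::export]]
List cpp_train_lvq1(NumericMatrix W, IntegerVector wlab,
                    NumericMatrix X, IntegerVector y,
                    NumericMatrix Xval, IntegerVector yval,
                    NumericVector lr, bool shuffle, int seed, int patience) {
  int nodes = W.nrow(), dim = W.ncol(), n = X.nrow(), nv = Xval.nrow();
  int epochs = lr.size();
  std::vector<double> Wv = to_row_major(W), Xv = to_row_major(X),
                      Vv = to_row_major(Xval);

  std::mt19937 gen((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> valq;
  valq.reserve(epochs);
  std::vector<double> Wbest = Wv;
  double bestq = -1.0;
  int best_epoch = 0;

  for (int e = 0; e < epochs; ++e) {
    double a = lr[e];
    if (shuffle) fy_shuffle(order, gen);
    for (int ii = 0; ii < n; ++ii) {
      int i = order[ii];
      const double* x = &Xv[(size_t)i * dim];
      int b = bmu_of(Wv, nodes, dim, x, nullptr);
      double s = (wlab[b] == y[i]) ? a : -a;
      double* w = &Wv[(size_t)b * dim];
      for (int j = 0; j < dim; ++j) w[j] += s * (x[j] - w[j]);
    }
    int correct = 0;
    for (int i = 0; i < nv; ++i) {
      int b = bmu_of(Wv, nodes, dim, &Vv[(size_t)i * dim], nullptr);
      if (wlab[b] == yval[i]) ++correct;
    }
    double q = (double)correct / nv;
    valq.push_back(q);
    if (q > bestq) { bestq = q; best_epoch = e; Wbest = Wv; }
    if (patience > 0 && e - best_epoch >= patience) break;
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["prototypes"] = from_row_major(Wbest, nodes, dim),
                      _["final_prototypes"] = from_row_major(Wv, nodes, dim),
                      _["best_epoch"] = best_epoch + 1,
                      _["val_quality"] = valq);
}
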
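#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shared k-nearest-neighbour search over the rows of a delay-vector library.
// Distances are accumulated column-by-column so that memory access follows
// R's column-major layout. Library rows are ordered by source time, so
// breaking distance ties by the smaller row index is the same as breaking
// them by the earlier source time.
static void knn_core(const NumericMatrix& queries, const NumericMatrix& lib,
                     const LogicalVector& eligible, const int kappa,
                     IntegerMatrix& out_idx, NumericMatrix& out_dist) {
  const int m = queries.nrow(), p = queries.ncol(), N = lib.nrow();
  if (lib.ncol() != p) stop("query and library dimensions differ");
  std::vector<int> cand;
  cand.reserve(N);
  for (int r = 0; r < N; ++r) if (eligible[r]) cand.push_back(r);
  const int nc = (int) cand.size();
  if (kappa > nc) stop("kappa exceeds the number of eligible library rows");
  const double* L = &lib(0, 0);
  const double* Qm = &queries(0, 0);
  std::vector<double> d2(nc);
  std::vector< std::pair<double,int> > best(nc);
  for (int q = 0; q < m; ++q) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int c = 0; c < p; ++c) {
      const double qc = Qm[q + (size_t) c * m];
      const double* col = L + (size_t) c * N;
      for (int j = 0; j < nc; ++j) {
        const double t = qc - col[cand[j]];
        d2[j] += t * t;
      }
    }
    for (int j = 0; j < nc; ++j) best[j] = std::make_pair(d2[j], cand[j]);
    // lexicographic pair order: distance first, then row index (deterministic)
    std::partial_sort(best.begin(), best.begin() + kappa, best.end());
    for (int k = 0; k < kappa; ++k) {
      out_idx(q, k) = best[k].second + 1;
      out_dist(q, k) = std::sqrt(best[k].first);
    }
  }
}

// [[Rcpp::export]]
List cpp_knn_query(NumericMatrix queries, NumericMatrix lib,
                   LogicalVector eligible, int kappa) {
  IntegerMatrix idx(queries.nrow(), kappa);
  NumericMatrix dist(queries.nrow(), kappa);
  knn_core(queries, lib, eligible, kappa, idx, dist);
  return List::create(_["indices"] = idx, _["dists"] = dist);
}

// [[Rcpp::export]]
NumericVector cpp_knn_predict(NumericMatrix queries, NumericMatrix lib,
                              NumericVector futures, LogicalVector eligible,
                              int kappa, int weighting) {
  const int m = queries.nrow();
  IntegerMatrix idx(m, kappa);
  NumericMatrix dist(m, kappa);
  knn_core(queries, lib, eligible, kappa, idx, dist);
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    if (weighting == 0) {                       // uniform: plain average
      double s = 0.0;
      for (int k = 0; k < kappa; ++k) s += futures[idx(q, k) - 1];
      out[q] = s / kappa;
    } else {                                    // inverse distance
      double s = 0.0, w = 0.0;
      for (int k = 0; k < kappa; ++k) {
        const double wk = 1.0 / std::max(dist(q, k), 1e-12);
        s += wk * futures[idx(q, k) - 1];
        w += wk;
      }
      out[q] = s / w;
    }
  }
  return out;
}
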
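#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>

using namespace Rcpp;

// Median of a small vector (average of middle two for even n), matching
// stats::median.
static double med(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Lloyd iterations for k-means under the cityblock (L1) distance with
// component-wise median centroid updates.  Xt is d x n (column =
// observation, for contiguous access); init holds 1-based observation
// indices seeding the centroids.  Empty clusters are re-seeded from the
// point farthest (L1) from its assigned centroid.
// [[Rcpp::export(name = ".km_cityblock")]]
List km_cityblock(const NumericMatrix& Xt, const IntegerVector& init,
                  int max_iter) {
  const int d = Xt.nrow(), n = Xt.ncol(), k = init.size();
  const double* x = REAL(Xt);
  std::vector<double> centers((size_t)d * k);
  for (int j = 0; j < k; ++j)
    std::copy(x + (size_t)d * (init[j] - 1), x + (size_t)d * init[j],
              centers.begin() + (size_t)d * j);
  IntegerVector labels(n, -1);
  std::vector<double> dist_own(n);
  std::vector<double> cost_history;
  double cost = 0.0;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    cost = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = x + (size_t)d * i;
      double best = std::numeric_limits<double>::infinity();
      int besti = 0;
      for (int j = 0; j < k; ++j) {
        const double* cj = &centers[(size_t)d * j];
        double s = 0.0;
        int c = 0;
        for (; c + 3 < d; c += 4) {
          s += std::abs(xi[c] - cj[c]) + std::abs(xi[c + 1] - cj[c + 1]) +
               std::abs(xi[c + 2] - cj[c + 2]) + std::abs(xi[c + 3] - cj[c + 3]);
          if (s >= best) break;
        }
        if (s < best) {
          for (; c < d; ++c) s += std::abs(xi[c] - cj[c]);
        }
        if (s < best) { best = s; besti = j; }
      }
      if (labels[i] != besti) { labels[i] = besti; changed = true; }
      dist_own[i] = best;
      cost += best;
    }
    cost_history.push_back(cost);
    if (!changed && iter > 0) break;
    // medians per cluster/dimension
    std::vector<std::vector<int> > members(k);
    for (int i = 0; i < n; ++i) members[labels[i]].push_back(i);
    for (int j = 0; j < k; ++j) {
      double* cj = &centers[(size_t)d * j];
      if (members[j].empty()) {
        // re-seed from the globally farthest point
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (dist_own[i] > fd) { fd = dist_own[i]; far = i; }
        std::copy(x + (size_t)d * far, x + (size_t)d * (far + 1), cj);
        dist_own[far] = 0.0;
        continue;
      }
      std::vector<double> buf(members[j].size());
      for (int c = 0; c < d; ++c) {
        for (size_t m = 0; m < members[j].size(); ++m)
          buf[m] = x[(size_t)d * members[j][m] + c];
        cj[c] = med(buf);
      }
    }
  }
  NumericMatrix centers_out(k, d);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) centers_out(j, c) = centers[(size_t)d * j + c];
  return List::create(_["labels"] = labels + 1, _["centers"] = centers_out,
                      _["cost"] = cost,
                      _["cost_history"] = wrap(cost_history),
                      _["iterations"] = iter + 1);
}
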
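// Exact nearest-neighbour search and per-point Gaussian kernel calibration.
// Distances are squared Euclidean throughout; ties broken by point index.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact k-nearest-neighbour search via blocked Gram-matrix computation.
// Returns 1-based neighbour indices and squared Euclidean distances,
// each row sorted by (distance, index); self excluded.
// [[Rcpp::export(name = ".knn_exact_cpp")]]
List knn_exact_cpp(const arma::mat& X, const int k, const int block = 512) {
  const int n = X.n_rows;
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  arma::vec sq = arma::sum(arma::square(X), 1);
  IntegerMatrix idx(n, k);
  NumericMatrix d2(n, k);

  std::vector<std::pair<double, int> > cand(n);
  for (int start = 0; start < n; start += block) {
    int stop_ = std::min(n, start + block);
    arma::mat G = X.rows(start, stop_ - 1) * X.t();  // b x n
    for (int r = start; r < stop_; ++r) {
      int m = 0;
      for (int j = 0; j < n; ++j) {
        if (j == r) continue;
        double d = sq[r] + sq[j] - 2.0 * G(r - start, j);
        if (d < 0) d = 0;
        cand[m++] = std::make_pair(d, j);
      }
      // nth_element (O(m)) then sort the k winners: much cheaper than
      // partial_sort's O(m log k) for the wide neighbourhoods used by
      // multi-scale affinities
      std::nth_element(cand.begin(), cand.begin() + (k - 1),
                       cand.begin() + m);
      std::sort(cand.begin(), cand.begin() + k);
      for (int c = 0; c < k; ++c) {
        idx(r, c) = cand[c].second + 1;
        d2(r, c) = cand[c].first;
      }
    }
  }
  return List::create(_["idx"] = idx, _["dist2"] = d2);
}

// Perplexity of a probability vector: exp of its Shannon entropy (nats).
static double row_perplexity(const std::vector<double>& p) {
  double h = 0.0;
  for (size_t j = 0; j < p.size(); ++j)
    if (p[j] > 0) h -= p[j] * std::log(p[j]);
  return std::exp(h);
}

// Gaussian kernel over squared distances at variance s2, normalised.
static void kernel_probs(const double* d2, int m, double s2,
                         std::vector<double>& p) {
  double dmin = d2[0];
  for (int j = 1; j < m; ++j) if (d2[j] < dmin) dmin = d2[j];
  double sum = 0.0;
  for (int j = 0; j < m; ++j) {
    p[j] = std::exp(-(d2[j] - dmin) / (2.0 * s2));
    sum += p[j];
  }
  for (int j = 0; j < m; ++j) p[j] /= sum;
}

// Calibrate each row's Gaussian bandwidth so that the perplexity of the
// resulting neighbour distribution hits the target, by bisection on
// log(sigma^2) over [log 1e-20, log 1e20].
// D2: n x k matrix of squared distances to the k nearest neighbours.
// Returns row-stochastic P (n x k), sigma (n), and achieved perplexity.
// [[Rcpp::export(name = ".calibrate_rows_cpp")]]
List calibrate_rows_cpp(const NumericMatrix& D2, const double perplexity,
                        const double tol = 1e-5, const int max_iter = 200) {
  const int n = D2.nrow(), k = D2.ncol();
  NumericMatrix P(n, k);
  NumericVector sigma(n), achieved(n);
  std::vector<double> p(k), d2(k);
  const double lo0 = std::log(1e-20), hi0 = std::log(1e20);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) d2[j] = D2(i, j);
    double lo = lo0, hi = hi0, mid = 0.0, perp = 0.0;
    for (int it = 0; it < max_iter; ++it) {
      mid = 0.5 * (lo + hi);
      kernel_probs(d2.data(), k, std::exp(mid), p);
      perp = row_perplexity(p);
      if (std::fabs(perp - perplexity) < tol) break;
      if (perp > perplexity) hi = mid; else lo = mid;
    }
    if (std::fabs(perp - perplexity) > tol) {
      // degenerate row (e.g. all-equal distances): perplexity unreachable
      sigma[i] = NA_REAL;
      achieved[i] = perp;
      continue;
    }
    sigma[i] = std::sqrt(std::exp(mid));
    achieved[i] = perp;
    for (int j = 0; j < k; ++j) P(i, j) = p[j];
  }
  return List::create(_["P"] = P, _["sigma"] = sigma,
                      _["achieved"] = achieved);
}
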
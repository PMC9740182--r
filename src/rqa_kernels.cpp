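#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euclidean distances between rows of two embedded-state matrices.
// [[Rcpp::export]]
NumericMatrix state_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("embedding dimensions differ");
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      out(i, j) = std::sqrt(s);
    }
  }
  return out;
}

// Threshold a distance matrix so that the fraction of eligible cells at or
// below epsilon equals target_rr (epsilon = empirical quantile of eligible
// distances). Eligible cells are those with |i - j| >= theiler; theiler = 0
// keeps every cell, theiler = 1 drops only the line of identity.
// [[Rcpp::export]]
List recurrence_threshold_cpp(NumericMatrix d, double target_rr, int theiler) {
  const int n = d.nrow(), m = d.ncol();
  std::vector<double> elig;
  elig.reserve((size_t)n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (std::abs(i - j) >= theiler) elig.push_back(d(i, j));
  const size_t K = elig.size();
  if (K == 0) stop("no eligible cells outside the Theiler window");
  double maxel = 0.0;
  for (size_t t = 0; t < K; ++t)
    if (elig[t] > maxel) maxel = elig[t];
  if (maxel == 0.0)
    stop("all pairwise distances are zero (constant series)");
  size_t k = (size_t)std::ceil(target_rr * (double)K);
  if (k < 1) k = 1;
  if (k > K) k = K;
  std::nth_element(elig.begin(), elig.begin() + (k - 1), elig.end());
  const double eps = elig[k - 1];
  IntegerMatrix rec(n, m);
  size_t hits = 0;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (std::abs(i - j) >= theiler && d(i, j) <= eps) {
        rec(i, j) = 1;
        ++hits;
      }
    }
  }
  return List::create(_["matrix"] = rec, _["epsilon"] = eps,
                      _["achieved_rr"] = (double)hits / (double)K,
                      _["n_eligible"] = (double)K);
}

// Exhaustive maximal-run histograms of a binary matrix: lengths of diagonal
// runs (all offsets) and vertical runs (all columns), plus per-offset
// recurrence counts and cell counts for the TREND statistic. Cells inside an
// excluded Theiler band are expected to be zero already, so runs break there
// naturally and empty diagonals contribute no lines.
// [[Rcpp::export]]
List line_histograms_cpp(IntegerMatrix rec) {
  const int n = rec.nrow(), m = rec.ncol();
  std::vector<int> diag_len, vert_len;
  std::vector<int> offs, counts, cells;

  for (int off = -(n - 1); off <= m - 1; ++off) {
    int i0 = off < 0 ? -off : 0;
    int j0 = off < 0 ? 0 : off;
    int run = 0, cnt = 0, len = 0;
    while (i0 < n && j0 < m) {
      ++len;
      if (rec(i0, j0) == 1) {
        ++run;
        ++cnt;
      } else if (run > 0) {
        diag_len.push_back(run);
        run = 0;
      }
      ++i0;
      ++j0;
    }
    if (run > 0) diag_len.push_back(run);
    offs.push_back(off);
    counts.push_back(cnt);
    cells.push_back(len);
  }

  for (int j = 0; j < m; ++j) {
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (rec(i, j) == 1) {
        ++run;
      } else if (run > 0) {
        vert_len.push_back(run);
        run = 0;
      }
    }
    if (run > 0) vert_len.push_back(run);
  }

  return List::create(_["diag_lengths"] = wrap(diag_len),
                      _["vert_lengths"] = wrap(vert_len),
                      _["offset"] = wrap(offs), _["offset_count"] = wrap(counts),
                      _["offset_cells"] = wrap(cells));
}

// Kennel false-nearest-neighbour fractions for m = 1..max_m. For each point
// the nearest neighbour (by Euclidean distance in the m-dimensional
// embedding, self excluded) is tested with the distance-ratio criterion
// (rtol) and the attractor-size criterion (atol, relative to the series sd).
// Only points with a defined (m+1)-th coordinate enter, so the fraction at m
// uses the first n - m*tau points.
// [[Rcpp::export]]
NumericVector fnn_fractions_cpp(NumericVector x, int tau, int max_m,
                                double rtol, double atol,
                                double stop_below = -1.0) {
  const int n = x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double sv = 0.0;
  for (int i = 0; i < n; ++i) sv += (x[i] - mean) * (x[i] - mean);
  const double sigma = std::sqrt(sv / (n - 1));
  if (sigma <= 0) stop("constant series: FNN undefined");

  NumericVector frac(max_m, NA_REAL);
  for (int m = 1; m <= max_m; ++m) {
    const int np = n - m * tau;  // points with an (m+1)-th coordinate
    if (np < 2) break;
    int nfalse = 0, nvalid = 0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < np; ++j) {
        if (j == i) continue;
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          const double diff = x[i + k * tau] - x[j + k * tau];
          s += diff * diff;
        }
        if (s < best) {
          best = s;
          bj = j;
        }
      }
      if (bj < 0) continue;
      // floor the neighbour distance at numerical-noise scale so duplicate
      // states of exactly periodic series are not judged by dust ratios
      const double floor_d = 1e-8 * sigma;
      const double dm = std::max(std::sqrt(best), floor_d);
      const double extra = std::abs(x[i + m * tau] - x[bj + m * tau]);
      ++nvalid;
      const double dm1 = std::sqrt(dm * dm + extra * extra);
      const bool is_false = (extra / dm > rtol) || (dm1 / sigma > atol);
      if (is_false) ++nfalse;
    }
    if (nvalid > 0) frac[m - 1] = (double)nfalse / (double)nvalid;
    // the search wants the smallest acceptable m; later fractions are unused
    if (stop_below >= 0 && nvalid > 0 && frac[m - 1] <= stop_below) break;
  }
  return frac;
}
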
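#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Median of a scratch vector (sorts in place; midpoint rule for even n).
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// constant * median(|x - median(x)|) on x[0..n). Matches stats::mad():
// sorting x first leaves the multiset of |x - med| unchanged.
static double mad_scaled(const double* x, int n, double constant,
                         std::vector<double>& buf) {
  buf.assign(x, x + n);
  const double med = median_inplace(buf);
  for (int i = 0; i < n; ++i) buf[i] = std::fabs(buf[i] - med);
  return constant * median_inplace(buf);
}

// Fisher-Yates using R's RNG so set.seed() governs reproducibility.
static void shuffle_rng(std::vector<double>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[(size_t)i], v[(size_t)j]);
  }
}

// [[Rcpp::export]]
double cpp_mad(NumericVector x, double constant) {
  std::vector<double> buf;
  return mad_scaled(x.begin(), x.size(), constant, buf);
}

// Null distribution of the range of group MADn under full label shuffles.
// sizes gives contiguous block lengths after each shuffle.
// [[Rcpp::export]]
NumericVector cpp_perm_null_madn_range(NumericVector x, IntegerVector sizes,
                                       int B, double constant) {
  const int n = x.size(), G = sizes.size();
  std::vector<double> pool(x.begin(), x.end()), buf;
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    shuffle_rng(pool);
    double lo = R_PosInf, hi = R_NegInf;
    int off = 0;
    for (int g = 0; g < G; ++g) {
      double m = mad_scaled(pool.data() + off, sizes[g], constant, buf);
      if (m < lo) lo = m;
      if (m > hi) hi = m;
      off += sizes[g];
    }
    out[b] = hi - lo;
    if (off != n) stop("group sizes do not sum to length(x)");
  }
  return out;
}

// Two-group null of |MADn_1 - MADn_2| (first n1 vs rest after shuffle).
// [[Rcpp::export]]
NumericVector cpp_perm_null_madn_diff(NumericVector x, int n1, int B,
                                      double constant) {
  const int n = x.size();
  std::vector<double> pool(x.begin(), x.end()), buf;
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    shuffle_rng(pool);
    double m1 = mad_scaled(pool.data(), n1, constant, buf);
    double m2 = mad_scaled(pool.data() + n1, n - n1, constant, buf);
    out[b] = std::fabs(m1 - m2);
  }
  return out;
}

// Two-group null of |mean_1 - mean_2|.
// [[Rcpp::export]]
NumericVector cpp_perm_null_mean_diff(NumericVector x, int n1, int B) {
  const int n = x.size();
  std::vector<double> pool(x.begin(), x.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += pool[(size_t)i];
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    shuffle_rng(pool);
    double s1 = 0.0;
    for (int i = 0; i < n1; ++i) s1 += pool[(size_t)i];
    out[b] = std::fabs(s1 / n1 - (total - s1) / (n - n1));
  }
  return out;
}

// Kruskal-Wallis H null from pre-ranked pooled values: ranks are invariant
// under label permutation, so only group rank sums change per shuffle.
// tie_factor is 1 - sum(t^3 - t)/(N^3 - N), applied as a divisor.
// [[Rcpp::export]]
NumericVector cpp_perm_null_kw(NumericVector ranks, IntegerVector sizes,
                               double tie_factor, int B) {
  const int n = ranks.size(), G = sizes.size();
  std::vector<double> pool(ranks.begin(), ranks.end());
  const double N = (double)n;
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    shuffle_rng(pool);
    double acc = 0.0;
    int off = 0;
    for (int g = 0; g < G; ++g) {
      double s = 0.0;
      for (int i = 0; i < sizes[g]; ++i) s += pool[(size_t)(off + i)];
      acc += s * s / sizes[g];
      off += sizes[g];
    }
    double H = 12.0 / (N * (N + 1.0)) * acc - 3.0 * (N + 1.0);
    out[b] = (tie_factor > 0) ? H / tie_factor : 0.0;
  }
  return out;
}

static int sample_index(int n) {
  int j = (int)(unif_rand() * n);
  return (j >= n) ? n - 1 : j;
}

// Bootstrap (resample with replacement) of MADn or the mean.
// stat: 0 = mad scaled by `constant`, 1 = mean.
// [[Rcpp::export]]
NumericVector cpp_boot_stat(NumericVector x, int B, int stat, double constant) {
  const int n = x.size();
  std::vector<double> res((size_t)n), buf;
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) res[(size_t)i] = x[sample_index(n)];
    if (stat == 0) {
      out[b] = mad_scaled(res.data(), n, constant, buf);
    } else {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += res[(size_t)i];
      out[b] = s / n;
    }
  }
  return out;
}

// Leave-one-out values of the same statistics, for jackknife acceleration.
// [[Rcpp::export]]
NumericVector cpp_jack_stat(NumericVector x, int stat, double constant) {
  const int n = x.size();
  std::vector<double> loo((size_t)n - 1), buf;
  NumericVector out(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  for (int i = 0; i < n; ++i) {
    if (stat == 1) {
      out[i] = (total - x[i]) / (n - 1);
      continue;
    }
    int k = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) loo[(size_t)k++] = x[j];
    out[i] = mad_scaled(loo.data(), n - 1, constant, buf);
  }
  return out;
}
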
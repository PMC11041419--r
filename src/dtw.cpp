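#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dynamic time warping, symmetric unit-weight step pattern: from cell (i,j)
// the path may arrive from (i-1,j), (i,j-1) or (i-1,j-1), each adding the
// local cost of (i,j) exactly once.  Returns the raw cumulative cost of the
// optimal monotone path from (1,1) to (n,m).  cost_type: 1 = |a-b| (L1),
// 2 = (a-b)^2 (squared L2).  band < 0 disables the Sakoe-Chiba constraint.
static double dtw_core(const double* a, int n, const double* b, int m,
                       int cost_type, int band) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = INF;
    int jlo = 1, jhi = m;
    if (band >= 0) {
      // band is measured in cells around the (scaled) diagonal of a
      // rectangular matrix; use the plain |i-j| <= band form.
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
      for (int j = 0; j < jlo; ++j) cur[j] = INF;
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      double c = (cost_type == 1) ? std::fabs(d) : d * d;
      double best = prev[j];                       // insertion
      if (cur[j - 1] < best) best = cur[j - 1];    // deletion
      if (prev[j - 1] < best) best = prev[j - 1];  // match
      cur[j] = c + best;
    }
    if (band >= 0) for (int j = jhi + 1; j <= m; ++j) cur[j] = INF;
    std::swap(prev, cur);
  }
  return prev[m];
}

static void znorm(std::vector<double>& x) {
  int n = (int)x.size();
  double mu = 0.0;
  for (double v : x) mu += v;
  mu /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - mu) * (v - mu);
  double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
  if (sd <= 0.0) sd = 1.0;
  for (double& v : x) v = (v - mu) / sd;
}

static std::vector<double> as_vec(SEXP s, bool normalize) {
  NumericVector v(s);
  std::vector<double> out(v.begin(), v.end());
  if (normalize) znorm(out);
  return out;
}

// [[Rcpp::export]]
double cpp_dtw_distance(NumericVector a, NumericVector b, int cost_type,
                        int band, bool normalize) {
  std::vector<double> x = as_vec(a, normalize), y = as_vec(b, normalize);
  return dtw_core(x.data(), (int)x.size(), y.data(), (int)y.size(),
                  cost_type, band);
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(List seqs, int cost_type, int band,
                             bool normalize) {
  int n = seqs.size();
  std::vector< std::vector<double> > xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as_vec(seqs[i], normalize);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(xs[i].data(), (int)xs[i].size(),
                          xs[j].data(), (int)xs[j].size(), cost_type, band);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_cross(List seqs_a, List seqs_b, int cost_type, int band,
                            bool normalize) {
  int n = seqs_a.size(), m = seqs_b.size();
  std::vector< std::vector<double> > xs(n), ys(m);
  for (int i = 0; i < n; ++i) xs[i] = as_vec(seqs_a[i], normalize);
  for (int j = 0; j < m; ++j) ys[j] = as_vec(seqs_b[j], normalize);
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      D(i, j) = dtw_core(xs[i].data(), (int)xs[i].size(),
                         ys[j].data(), (int)ys[j].size(), cost_type, band);
  return D;
}
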
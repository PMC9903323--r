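#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a scratch buffer; midpoint convention for even counts
static double buf_median(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + h);
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf;
  buf.reserve(nr);
  for (int j = 0; j < nc; ++j) {
    buf.clear();
    for (int i = 0; i < nr; ++i) {
      double v = x(i, j);
      if (R_finite(v)) buf.push_back(v);
    }
    out[j] = buf_median(buf);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    for (int j = 0; j < nc; ++j) {
      double v = x(i, j);
      if (R_finite(v)) buf.push_back(v);
    }
    out[i] = buf_median(buf);
  }
  return out;
}

// Pairwise sample-to-sample log-ratios for one protein's peptide submatrix.
// ratio(j,k) = median over peptides observed in both samples of x(,k) - x(,j);
// count(j,k) = number of shared peptides. NA ratio when no peptide is shared.
// [[Rcpp::export]]
List cpp_pairwise_ratio_medians(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix ratio(nc, nc);
  IntegerMatrix count(nc, nc);
  std::vector<double> buf;
  buf.reserve(nr);
  std::fill(ratio.begin(), ratio.end(), NA_REAL);
  for (int j = 0; j < nc; ++j) ratio(j, j) = 0.0;
  for (int j = 0; j < nc - 1; ++j) {
    for (int k = j + 1; k < nc; ++k) {
      buf.clear();
      for (int i = 0; i < nr; ++i) {
        double a = x(i, j), b = x(i, k);
        if (R_finite(a) && R_finite(b)) buf.push_back(b - a);
      }
      count(j, k) = count(k, j) = (int)buf.size();
      if (!buf.empty()) {
        double m = buf_median(buf);
        ratio(j, k) = m;
        ratio(k, j) = -m;
      }
    }
  }
  return List::create(_["ratio"] = ratio, _["count"] = count);
}
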
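#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Map index onto 0..n-1 by reflection (symmetric padding without repeating
// the edge point twice beyond one reflection; traces are far longer than
// any window used here).
static inline int reflect(int i, int n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// Centered moving median with reflected padding. For even windows the
// window is left-biased: it covers i - w/2 .. i + w/2 - 1.
// [[Rcpp::export(name = ".runningMedian")]]
NumericVector runningMedian(NumericVector x, int window) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  if (window > n) stop("window exceeds trace length");
  NumericVector out(n);
  int lo = -(window / 2);                  // left-biased for even windows
  int hi = lo + window - 1;
  std::vector<double> buf(window);
  for (int i = 0; i < n; ++i) {
    for (int j = lo; j <= hi; ++j) buf[j - lo] = x[reflect(i + j, n)];
    std::vector<double> b = buf;
    int m = window / 2;
    std::nth_element(b.begin(), b.begin() + m, b.end());
    double med = b[m];
    if (window % 2 == 0) {
      std::nth_element(b.begin(), b.begin() + m - 1, b.end());
      med = 0.5 * (med + b[m - 1]);
    }
    out[i] = med;
  }
  return out;
}

// Flat-structuring-element erosion (running min) with reflected padding;
// element covers i - (k-1)/2 .. i + k/2 for even k (left-biased center).
static NumericVector runExtreme(NumericVector x, int k, bool takeMin) {
  int n = x.size();
  if (k < 1) stop("element size must be >= 1");
  NumericVector out(n);
  int lo = -((k - 1) / 2);
  int hi = lo + k - 1;
  for (int i = 0; i < n; ++i) {
    double v = x[reflect(i + lo, n)];
    for (int j = lo + 1; j <= hi; ++j) {
      double xv = x[reflect(i + j, n)];
      if (takeMin ? (xv < v) : (xv > v)) v = xv;
    }
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".runningMin")]]
NumericVector runningMin(NumericVector x, int k) { return runExtreme(x, k, true); }

// [[Rcpp::export(name = ".runningMax")]]
NumericVector runningMax(NumericVector x, int k) { return runExtreme(x, k, false); }
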
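#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window median with missing-value discarding.
//
// Window for step i (0-based) is steps [i - w/2, i + w/2 - 1], truncated at
// the ends of the vector.  NA values do not contribute; when fewer than
// min_points non-NA values remain the output is NA.  Even-count windows
// take the lower of the two central order statistics so the result is
// always an observed value and the smoother is monotone.
// [[Rcpp::export]]
NumericVector sliding_median(NumericVector x, int w, int min_points) {
  const int n = x.size();
  NumericVector out(n, NA_REAL);
  const int left = w / 2;
  const int right = w - left - 1;
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i < n; ++i) {
    int lo = i - left;
    int hi = i + right;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    buf.clear();
    for (int j = lo; j <= hi; ++j) {
      double v = x[j];
      if (!ISNAN(v)) buf.push_back(v);
    }
    const int c = static_cast<int>(buf.size());
    if (c < min_points || c == 0) continue;
    const int k = (c + 1) / 2 - 1;  // lower median, 0-based
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    out[i] = buf[k];
  }
  return out;
}
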
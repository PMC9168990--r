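#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window extreme over an irregular m/z axis: for each i, the
// min (or max) of x[j] over all j with |mz[j] - mz[i]| <= half.
// Monotonic-deque algorithm, O(n); mz must be non-decreasing.
// [[Rcpp::export]]
NumericVector c_roll_extreme(NumericVector mz, NumericVector x,
                             double half, bool maximum) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> dq;
  int hi = -1;
  for (int i = 0; i < n; ++i) {
    double lo_mz = mz[i] - half, hi_mz = mz[i] + half;
    while (hi + 1 < n && mz[hi + 1] <= hi_mz) {
      ++hi;
      while (!dq.empty() &&
             (maximum ? x[dq.back()] <= x[hi] : x[dq.back()] >= x[hi]))
        dq.pop_back();
      dq.push_back(hi);
    }
    while (!dq.empty() && mz[dq.front()] < lo_mz) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}
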
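#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// reflective index into [0, n-1] (mirror without repeating the edge sample,
// falling back to clamping for very small images)
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Lower-median k x k filter. For odd k the window is centered; for even k the
// output pixel sits at the top-left of the window's central 2 x 2 block, i.e.
// offsets -(k/2 - 1) .. k/2 in both directions. Padding is reflective and the
// lower median (element ceil(k^2 / 2) of the sorted window) is returned, so
// the result is reproducible by exhaustive enumeration.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  int nr = img.nrow(), nc = img.ncol();
  int lo = (k % 2 == 0) ? -(k / 2 - 1) : -(k - 1) / 2;
  int hi = k / 2;
  int n = k * k;
  int med = (n + 1) / 2 - 1; // 0-based index of the lower median
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = 0;
      for (int dc = lo; dc <= hi; ++dc) {
        int cc = reflect_index(c + dc, nc);
        for (int dr = lo; dr <= hi; ++dr) {
          int rr = reflect_index(r + dr, nr);
          buf[idx++] = img(rr, cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + med, buf.end());
      out(r, c) = buf[med];
    }
  }
  return out;
}

// 8-connected component labeling of a binary mask (non-zero = foreground).
// Labels are positive integers in scan order of the first pixel encountered;
// background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
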
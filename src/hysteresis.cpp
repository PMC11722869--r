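#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Hysteresis edge linking: flood-fill the weak mask from strong seed pixels
// using 8-connectivity. `weak` must include the strong pixels.
// [[Rcpp::export]]
IntegerMatrix hysteresis_fill(LogicalMatrix strong, LogicalMatrix weak) {
  const int nr = strong.nrow(), nc = strong.ncol();
  if (weak.nrow() != nr || weak.ncol() != nc)
    stop("strong/weak shape mismatch");
  IntegerMatrix out(nr, nc);
  std::vector<std::pair<int, int> > stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!strong(r, c) || out(r, c)) continue;
      out(r, c) = 1;
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            const int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            if (!out(rr, cc) && weak(rr, cc)) {
              out(rr, cc) = 1;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return out;
}
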
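#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by stack-based flood fill.
// connectivity must be 4 or 8; labels are assigned in column-major scan order.
// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int ndir = (connectivity == 8) ? 8 : 4;
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        lab(r, c) = ++next;
        stack.push_back(std::make_pair(r, c));
        while (!stack.empty()) {
          std::pair<int, int> rc = stack.back();
          stack.pop_back();
          for (int k = 0; k < ndir; ++k) {
            int rr = rc.first + dr[k], cc = rc.second + dc[k];
            if (rr >= 0 && rr < H && cc >= 0 && cc < W &&
                mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-pixel median across the third dimension of an H x W x N array.
// Even N uses the mean of the two middle order statistics.
// [[Rcpp::export]]
NumericMatrix median_stack(NumericVector frames) {
  IntegerVector d = frames.attr("dim");
  if (d.size() != 3) stop("frames must be an H x W x N array");
  const int H = d[0], W = d[1], N = d[2];
  NumericMatrix out(H, W);
  std::vector<double> buf(N);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (R_xlen_t p = 0; p < HW; ++p) {
    for (int t = 0; t < N; ++t) buf[t] = frames[p + (R_xlen_t)t * HW];
    const int m = N / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double v = buf[m];
    if (N % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
      v = 0.5 * (v + buf[m - 1]);
    }
    out[p] = v;
  }
  return out;
}
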
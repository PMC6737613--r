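#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conditioned spatio-temporal average over an N x N x K causal mask.
//
// frames: (T, H, W) array in R column-major order, index t + T*(y + H*x).
// thresh: per-pixel inclusion threshold evaluated at the center pixel's
//         observed value; length 1 (recycled, used for the plain moving
//         average with thresh = +Inf) or same length as frames.
// For each pixel, neighbors at spatial offsets j, h in [-(N-1)/2, (N-1)/2]
// and temporal offsets i in [0, K-1] into the past are admitted when they
// are in bounds and |neighbor - center| <= thresh; the output is the mean
// of the admitted neighbors. The center always qualifies, so the
// denominator is >= 1. Deviations from the center are accumulated
// (center + sum(v - c)/n), so constant neighborhoods are exact fixed
// points in floating point. Accumulation order is i, then j, then h,
// matching the reference R oracle bit for bit.
// [[Rcpp::export]]
NumericVector nvca_core(const NumericVector& frames, const IntegerVector& dims,
                        const NumericVector& thresh, const int n_spatial,
                        const int k_temporal) {
  const int T = dims[0], H = dims[1], W = dims[2];
  const int r = (n_spatial - 1) / 2;
  const bool scalar_t = (thresh.size() == 1);
  NumericVector out(frames.size());

  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      for (int t = 0; t < T; ++t) {
        const R_xlen_t idx = t + (R_xlen_t)T * (y + (R_xlen_t)H * x);
        const double c = frames[idx];
        const double tt = scalar_t ? thresh[0] : thresh[idx];
        double s = 0.0;
        int cnt = 0;
        for (int i = 0; i < k_temporal; ++i) {
          const int ti = t - i;
          if (ti < 0) continue;
          for (int j = -r; j <= r; ++j) {
            const int yj = y - j;
            if (yj < 0 || yj >= H) continue;
            for (int hh = -r; hh <= r; ++hh) {
              const int xh = x - hh;
              if (xh < 0 || xh >= W) continue;
              const double v =
                  frames[ti + (R_xlen_t)T * (yj + (R_xlen_t)H * xh)];
              if (std::abs(v - c) <= tt) {
                s += v - c;
                ++cnt;
              }
            }
          }
        }
        out[idx] = c + s / cnt;
      }
    }
  }
  return out;
}
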
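#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// Separable correlation with replicate (edge-clamp) padding.
// kr runs down rows, kc across columns; both are applied as correlations
// (no kernel flip), so an odd antisymmetric kernel gives a forward derivative.
// [[Rcpp::export]]
NumericMatrix conv_sep_replicate(NumericMatrix img, NumericVector kr, NumericVector kc) {
  const int h = img.nrow(), w = img.ncol();
  const int nr = kr.size(), nc = kc.size();
  const int cr = nr / 2, cc = nc / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      double s = 0.0;
      for (int j = 0; j < nc; ++j)
        s += kc[j] * img(r, clampi(c + j - cc, 0, w - 1));
      tmp(r, c) = s;
    }
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      double s = 0.0;
      for (int i = 0; i < nr; ++i)
        s += kr[i] * tmp(clampi(r + i - cr, 0, h - 1), c);
      out(r, c) = s;
    }
  return out;
}

// Non-maximum suppression on the gradient magnitude. Angles in degrees,
// gradient direction measured from the horizontal axis with rows increasing
// downward; reduced mod 180 and quantized to 4 discrete directions.
// [[Rcpp::export]]
NumericMatrix canny_nms(NumericMatrix mag, NumericMatrix ang) {
  const int h = mag.nrow(), w = mag.ncol();
  NumericMatrix out(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      double m = mag(r, c);
      if (m <= 0.0) { out(r, c) = 0.0; continue; }
      double a = ang(r, c);
      a -= 180.0 * std::floor(a / 180.0);  // reduce to [0, 180)
      int dr1, dc1;
      if (a < 22.5 || a >= 157.5)      { dr1 = 0; dc1 = 1; }   // horizontal gradient
      else if (a < 67.5)               { dr1 = 1; dc1 = 1; }   // 45 deg (down-right)
      else if (a < 112.5)              { dr1 = 1; dc1 = 0; }   // vertical gradient
      else                             { dr1 = 1; dc1 = -1; }  // 135 deg (down-left)
      double m1 = mag(clampi(r + dr1, 0, h - 1), clampi(c + dc1, 0, w - 1));
      double m2 = mag(clampi(r - dr1, 0, h - 1), clampi(c - dc1, 0, w - 1));
      // strict > against one side breaks plateaus into single-pixel ridges
      out(r, c) = (m >= m1 && m > m2) ? m : 0.0;
    }
  return out;
}

// Hysteresis tracking: keep weak pixels 8-connected to a strong pixel.
// [[Rcpp::export]]
LogicalMatrix hysteresis_track(LogicalMatrix strong, LogicalMatrix weak) {
  const int h = strong.nrow(), w = strong.ncol();
  LogicalMatrix out(h, w);
  std::vector<int> stack;
  stack.reserve(256);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c)
      if (strong(r, c)) { out(r, c) = true; stack.push_back(r * w + c); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p / w, c = p % w;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
        if (!out(rr, cc) && weak(rr, cc)) {
          out(rr, cc) = true;
          stack.push_back(rr * w + cc);
        }
      }
  }
  return out;
}

static inline double cubic_keys(double x) {
  // Keys bicubic kernel, a = -0.5 (Catmull-Rom)
  const double a = -0.5;
  x = std::fabs(x);
  if (x < 1.0) return (a + 2.0) * x * x * x - (a + 3.0) * x * x + 1.0;
  if (x < 2.0) return a * x * x * x - 5.0 * a * x * x + 8.0 * a * x - 4.0 * a;
  return 0.0;
}

// Resample to out_h x out_w. method: 0 nearest, 1 bilinear, 2 bicubic.
// corner_anchor: integer-factor alignment src = dst / factor (LR (i,j) maps
// to HR (k*i, k*j)); otherwise center-aligned src = (dst + 0.5)/factor - 0.5.
// Nearest always uses pixel replication src = floor(dst / factor).
// [[Rcpp::export]]
NumericMatrix resample_grid(NumericMatrix img, int out_h, int out_w,
                            double factor, int method, bool corner_anchor) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  if (method == 0) {
    for (int r = 0; r < out_h; ++r) {
      int sr = clampi((int)std::floor(r / factor + 1e-9), 0, h - 1);
      for (int c = 0; c < out_w; ++c) {
        int sc = clampi((int)std::floor(c / factor + 1e-9), 0, w - 1);
        out(r, c) = img(sr, sc);
      }
    }
    return out;
  }
  for (int r = 0; r < out_h; ++r) {
    double sy = corner_anchor ? r / factor : (r + 0.5) / factor - 0.5;
    for (int c = 0; c < out_w; ++c) {
      double sx = corner_anchor ? c / factor : (c + 0.5) / factor - 0.5;
      double v = 0.0;
      if (method == 1) {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double fy = sy - y0, fx = sx - x0;
        int y1 = clampi(y0 + 1, 0, h - 1), x1 = clampi(x0 + 1, 0, w - 1);
        y0 = clampi(y0, 0, h - 1); x0 = clampi(x0, 0, w - 1);
        v = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
            fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      } else {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        // accumulate deviations from the nearest sample so that constant
        // neighbourhoods are reproduced bit-exactly despite rounding
        double v0 = img(clampi(y0, 0, h - 1), clampi(x0, 0, w - 1));
        double num = 0.0, den = 0.0;
        for (int i = -1; i <= 2; ++i) {
          double wy = cubic_keys(sy - (y0 + i));
          if (wy == 0.0) continue;
          for (int j = -1; j <= 2; ++j) {
            double wx = cubic_keys(sx - (x0 + j));
            if (wx == 0.0) continue;
            num += wy * wx * (img(clampi(y0 + i, 0, h - 1), clampi(x0 + j, 0, w - 1)) - v0);
            den += wy * wx;
          }
        }
        v = den != 0.0 ? v0 + num / den : v0;
      }
      out(r, c) = clamp01(v);
    }
  }
  return out;
}

// Solve the 4x4 system A w = b by Gaussian elimination with partial
// pivoting. Returns false when near-singular (covariance rank deficient).
static bool solve4(double A[4][4], double b[4], double w[4], double reg) {
  int idx[4] = {0, 1, 2, 3};
  double scale = 0.0;
  for (int i = 0; i < 4; ++i) scale = std::max(scale, std::fabs(A[i][i]));
  if (scale <= 0.0) return false;
  // a pivot at the level of the diagonal loading signals a rank-deficient
  // (e.g. locally planar) covariance: decline and let the caller fall back
  double tol = std::max(1e-8 * scale, 10.0 * reg);
  for (int k = 0; k < 4; ++k) {
    int p = k;
    for (int i = k + 1; i < 4; ++i)
      if (std::fabs(A[idx[i]][k]) > std::fabs(A[idx[p]][k])) p = i;
    std::swap(idx[k], idx[p]);
    double piv = A[idx[k]][k];
    if (std::fabs(piv) < tol) return false;
    for (int i = k + 1; i < 4; ++i) {
      double f = A[idx[i]][k] / piv;
      for (int j = k; j < 4; ++j) A[idx[i]][j] -= f * A[idx[k]][j];
      b[idx[i]] -= f * b[idx[k]];
    }
  }
  for (int k = 3; k >= 0; --k) {
    double s = b[idx[k]];
    for (int j = k + 1; j < 4; ++j) s -= A[idx[k]][j] * w[j];
    w[k] = s / A[idx[k]][k];
  }
  return true;
}

// One x2 doubling of the covariance-based edge-directed interpolator.
// Pass 1 fills the diagonal lattice (odd,odd) from the 4 diagonal neighbours;
// pass 2 fills the remaining (odd parity) pixels from the 4 cross neighbours.
// Four-tap weights are trained by least squares on a win x win low-resolution
// window (geometric duality between the coarse and fine lattices). Smooth or
// rank-deficient windows fall back to the 4-neighbour average.
// [[Rcpp::export]]
List nedi_double(NumericMatrix img, int win, double variance_floor, double reg) {
  const int h = img.nrow(), w = img.ncol();
  const int H = 2 * h, W = 2 * w;
  NumericMatrix out(H, W);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      out(2 * i, 2 * j) = img(i, j);

  const int half = win / 2;
  long filled = 0, fell = 0;
  double y[64], C[64][4];

  for (int pass = 0; pass < 2; ++pass) {
    // neighbour offsets on the HR grid (distance 1) and the dual offsets on
    // the LR grid (same directions, LR spacing)
    int ndr[4], ndc[4];
    if (pass == 0) { ndr[0] = -1; ndc[0] = -1; ndr[1] = -1; ndc[1] = 1;
                     ndr[2] = 1;  ndc[2] = -1; ndr[3] = 1;  ndc[3] = 1; }
    else           { ndr[0] = -1; ndc[0] = 0;  ndr[1] = 1;  ndc[1] = 0;
                     ndr[2] = 0;  ndc[2] = -1; ndr[3] = 0;  ndc[3] = 1; }
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        bool target = (pass == 0) ? (r % 2 == 1 && c % 2 == 1)
                                  : ((r + c) % 2 == 1);
        if (!target) continue;
        ++filled;
        // application neighbours; only in-bounds ones are filled at this
        // point, so the fallback averages those alone
        double nb[4];
        bool in_bounds = true;
        double nbsum = 0.0;
        int nbcnt = 0;
        for (int k = 0; k < 4; ++k) {
          int rr = r + ndr[k], cc = c + ndc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            in_bounds = false;
            nb[k] = 0.0;
          } else {
            nb[k] = out(rr, cc);
            nbsum += nb[k];
            ++nbcnt;
          }
        }
        double fallback = nbcnt > 0 ? nbsum / nbcnt : 0.0;
        int i0 = r / 2, j0 = c / 2;
        bool ok = in_bounds &&
                  i0 - half + 1 >= 1 && i0 + half <= h - 2 &&
                  j0 - half + 1 >= 1 && j0 + half <= w - 2;
        if (ok) {
          int n = 0;
          double mean = 0.0;
          for (int i = i0 - half + 1; i <= i0 + half; ++i)
            for (int j = j0 - half + 1; j <= j0 + half; ++j) {
              y[n] = img(i, j);
              mean += y[n];
              for (int k = 0; k < 4; ++k)
                C[n][k] = img(i + ndr[k], j + ndc[k]);
              ++n;
            }
          mean /= n;
          double var = 0.0;
          for (int t = 0; t < n; ++t) var += (y[t] - mean) * (y[t] - mean);
          var /= n;
          if (var < variance_floor) ok = false;
          if (ok) {
            double A[4][4], b[4], wt[4];
            for (int a = 0; a < 4; ++a) {
              b[a] = 0.0;
              for (int bb = 0; bb < 4; ++bb) A[a][bb] = 0.0;
            }
            for (int t = 0; t < n; ++t)
              for (int a = 0; a < 4; ++a) {
                b[a] += C[t][a] * y[t];
                for (int bb = 0; bb < 4; ++bb) A[a][bb] += C[t][a] * C[t][bb];
              }
            for (int a = 0; a < 4; ++a) A[a][a] += reg;
            if (solve4(A, b, wt, reg)) {
              double mag = std::fabs(wt[0]) + std::fabs(wt[1]) +
                           std::fabs(wt[2]) + std::fabs(wt[3]);
              if (mag <= 10.0) {
                out(r, c) = clamp01(wt[0] * nb[0] + wt[1] * nb[1] +
                                    wt[2] * nb[2] + wt[3] * nb[3]);
                continue;
              }
            }
          }
        }
        ++fell;
        out(r, c) = clamp01(fallback);
      }
  }
  return List::create(_["pixels"] = out,
                      _["fallback_rate"] = filled > 0 ? (double)fell / filled : 1.0);
}

// CRC-32 (ISO 3309 / PNG) over a raw vector, with an optional running value
// so multi-part chunks can be accumulated. Returns the CRC as a double.
// [[Rcpp::export]]
double crc32_raw(RawVector data, double init = 0.0) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
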
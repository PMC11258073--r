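#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Volumes are stored as R arrays with dim (D, H, W[, C]) in column-major
// order: D (axial, z) is the fastest index. All kernels below assume that
// layout and stride-1 "same" convolutions with zero padding.

static inline R_xlen_t idx3(int d, int h, int w, int D, int H) {
  return (R_xlen_t)d + (R_xlen_t)D * ((R_xlen_t)h + (R_xlen_t)H * (R_xlen_t)w);
}

// im2col for a k x k x k stride-1 same-padded 3D convolution.
// x: (D, H, W, Cin). Returns (Cin*k^3) x (D*H*W); row index runs over
// (kd, kh, kw, c) with kd fastest, so a weight matrix (Cout x Cin*k^3)
// built with the same ordering gives y = W %*% col.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int pad = k / 2, kk = k * k * k;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericMatrix col((R_xlen_t)C * kk, N);
  const double* xp = REAL(x);
  double* cp = REAL(col);
  const R_xlen_t chan_stride = N;          // channel stride within x
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const R_xlen_t out = idx3(d, h, w, D, H);
        double* colcol = cp + out * (R_xlen_t)(C * kk);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + c * chan_stride;
          for (int kw = 0; kw < k; ++kw) {
            const int ww = w + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              const int hh = h + kh - pad;
              for (int kd = 0; kd < k; ++kd, ++r) {
                const int dd = d + kd - pad;
                colcol[r] = (dd < 0 || dd >= D || hh < 0 || hh >= H ||
                             ww < 0 || ww >= W)
                              ? 0.0
                              : xc[idx3(dd, hh, ww, D, H)];
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of cpp_im2col3: scatter a (Cin*k^3) x N column matrix back into
// an input-shaped gradient. Row ordering must match cpp_im2col3.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix col, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int pad = k / 2, kk = k * k * k;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericVector out((R_xlen_t)C * N);
  double* op = REAL(out);
  const double* cp = REAL(col);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const R_xlen_t o = idx3(d, h, w, D, H);
        const double* colcol = cp + o * (R_xlen_t)(C * kk);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double* oc = op + c * N;
          for (int kw = 0; kw < k; ++kw) {
            const int ww = w + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              const int hh = h + kh - pad;
              for (int kd = 0; kd < k; ++kd, ++r) {
                const int dd = d + kd - pad;
                if (dd >= 0 && dd < D && hh >= 0 && hh < H && ww >= 0 &&
                    ww < W)
                  oc[idx3(dd, hh, ww, D, H)] += colcol[r];
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

// 2x2x2 max pooling, stride 2. Odd trailing extents are truncated (the
// network only sees extents divisible by 2^levels). Returns pooled values
// and 1-based argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W, No = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(No * C);
  IntegerVector amax(No * C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(amax);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * N;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -HUGE_VAL;
          R_xlen_t bi = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                R_xlen_t i = idx3(2 * d + kd, 2 * h + kh, 2 * w + kw, D, H);
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          R_xlen_t o = idx3(d, h, w, Do, Ho) + c * No;
          yp[o] = best;
          ap[o] = (int)(bi + c * N) + 1;
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_bwd(NumericVector dy, IntegerVector argmax,
                               IntegerVector in_dims) {
  const R_xlen_t N = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] *
                     in_dims[3];
  NumericVector dx(N);
  double* dp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ap = INTEGER(argmax);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[ap[i] - 1] += dyp[i];
  dx.attr("dim") = in_dims;
  return dx;
}

// ---- Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over axes with per-axis physical spacing. Input: 0/1 mask;
// output: squared distance (mm^2) from every voxel to the nearest voxel
// where mask == 0. Voxels of an all-foreground volume get +Inf.
static void edt_1d(std::vector<double>& f, std::vector<double>& d, int n,
                   double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = step * step;
  int kk = 0;
  v[0] = 0; z[0] = -HUGE_VAL; z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[kk];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q; z[kk] = s; z[kk + 1] = HUGE_VAL;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const int p = v[kk];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericVector out(N);
  double* g = REAL(out);
  const int* m = INTEGER(mask);
  // finite "infinity": HUGE_VAL breaks the parabola intersections
  const double BIG = 1e20;
  for (R_xlen_t i = 0; i < N; ++i) g[i] = m[i] ? BIG : 0.0;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax);
  // axis 0 (D, fastest)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      R_xlen_t base = idx3(0, h, w, D, H);
      for (int i = 0; i < D; ++i) f[i] = g[base + i];
      edt_1d(f, d, D, spacing[0]);
      for (int i = 0; i < D; ++i) g[base + i] = d[i];
    }
  // axis 1 (H)
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      for (int i = 0; i < H; ++i) f[i] = g[idx3(dd, i, w, D, H)];
      edt_1d(f, d, H, spacing[1]);
      for (int i = 0; i < H; ++i) g[idx3(dd, i, w, D, H)] = d[i];
    }
  // axis 2 (W)
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      for (int i = 0; i < W; ++i) f[i] = g[idx3(dd, h, i, D, H)];
      edt_1d(f, d, W, spacing[2]);
      for (int i = 0; i < W; ++i) g[idx3(dd, h, i, D, H)] = d[i];
    }
  out.attr("dim") = dims;
  return out;
}

// ---- Connected components on a 0/1 mask, 6- or 26-connectivity.
// Labels are assigned in increasing order of the first (column-major)
// voxel encountered; returns the label volume and component sizes.
// [[Rcpp::export]]
List cpp_label_cc(IntegerVector mask, IntegerVector dims, int connectivity) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector lab(N);
  const int* m = INTEGER(mask);
  int* L = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  std::vector<double> sizes;
  int next = 0;
  std::vector<std::array<int, 3>> nb;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (dd == 0 && dh == 0 && dw == 0) continue;
        int manh = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dd, dh, dw});
      }
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!m[s] || L[s]) continue;
    ++next;
    double sz = 0;
    stack.push_back(s);
    L[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++sz;
      int d = (int)(cur % D);
      int rem = (int)(cur / D);
      int h = rem % H, w = rem / H;
      for (auto& o : nb) {
        int dd = d + o[0], hh = h + o[1], ww = w + o[2];
        if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
          continue;
        R_xlen_t q = idx3(dd, hh, ww, D, H);
        if (m[q] && !L[q]) { L[q] = next; stack.push_back(q); }
      }
    }
    sizes.push_back(sz);
  }
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}
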
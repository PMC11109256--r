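#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 4-connected component labeling with union-find.
// Labels are renumbered 1..n_components in first-encounter (column-major) order.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix cc_label4(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!m(h, w)) continue;
      int up = (h > 0) ? lab(h - 1, w) : 0;
      int left = (w > 0) ? lab(h, w - 1) : 0;
      if (up == 0 && left == 0) {
        parent.push_back(next);
        lab(h, w) = next++;
      } else if (up != 0 && left != 0) {
        int ru = uf_find(parent, up), rl = uf_find(parent, left);
        lab(h, w) = ru < rl ? ru : rl;
        if (ru != rl) parent[ru > rl ? ru : rl] = (ru < rl ? ru : rl);
      } else {
        lab(h, w) = up + left;  // the nonzero one
      }
    }
  }
  // second pass: flatten and renumber
  std::vector<int> newid(parent.size(), 0);
  int k = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      int l = lab(h, w);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newid[r] == 0) newid[r] = ++k;
      lab(h, w) = newid[r];
    }
  return lab;
}

static inline int outdim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// 2-D multi-channel convolution (cross-correlation), zero padding.
// x: (H, W, Cin, N), w: (KH, KW, Cin, Cout), b: length Cout.
// [[Rcpp::export]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& b, int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Co = dw[3];
  if (dw[2] != Ci) stop("kernel input channels do not match input");
  const int Ho = outdim(H, KH, stride, pad), Wo = outdim(W, KW, stride, pad);
  NumericVector out(Ho * Wo * Co * (R_xlen_t)N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const int kw_lo = w0 < 0 ? -w0 : 0;
        const int kw_hi = (W - w0) < KW ? (W - w0) : KW;
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[co];
          const int h0 = ho * stride - pad;
          const int kh_lo = h0 < 0 ? -h0 : 0;
          const int kh_hi = (H - h0) < KH ? (H - h0) : KH;
          for (int ci = 0; ci < Ci; ++ci) {
            const double* xc = px + ((R_xlen_t)n * Ci + ci) * H * W;
            const double* wc = pw + ((R_xlen_t)co * Ci + ci) * KH * KW;
            for (int kw = kw_lo; kw < kw_hi; ++kw) {
              const double* xcol = xc + (R_xlen_t)(w0 + kw) * H + h0;
              const double* wcol = wc + kw * KH;
              for (int kh = kh_lo; kh < kh_hi; ++kh)
                acc += xcol[kh] * wcol[kh];
            }
          }
          po[ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (co + (R_xlen_t)Co * n))] = acc;
        }
      }
    }
  }
  return out;
}

// Gradients of conv2d_fwd. dout: (Ho, Wo, Cout, N).
// Returns list(dx, dw, db); dx omitted (NULL) when need_dx is false.
// [[Rcpp::export]]
List conv2d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& dout, int stride, int pad, bool need_dx) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim"), dd = dout.attr("dim");
  const int H = dx_[0], W = dx_[1], Ci = dx_[2], N = dx_[3];
  const int KH = dw_[0], KW = dw_[1], Co = dw_[3];
  const int Ho = dd[0], Wo = dd[1];
  NumericVector dw(w.size());
  dw.attr("dim") = dw_;
  NumericVector db(Co);
  NumericVector dxv(need_dx ? x.size() : 0);
  if (need_dx) dxv.attr("dim") = dx_;
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pd = dout.begin();
  double* pdw = dw.begin();
  double* pdx = need_dx ? dxv.begin() : (double*)nullptr;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const int kw_lo = w0 < 0 ? -w0 : 0;
        const int kw_hi = (W - w0) < KW ? (W - w0) : KW;
        for (int ho = 0; ho < Ho; ++ho) {
          const double g =
              pd[ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (co + (R_xlen_t)Co * n))];
          if (g == 0.0) continue;
          db[co] += g;
          const int h0 = ho * stride - pad;
          const int kh_lo = h0 < 0 ? -h0 : 0;
          const int kh_hi = (H - h0) < KH ? (H - h0) : KH;
          for (int ci = 0; ci < Ci; ++ci) {
            const double* xc = px + ((R_xlen_t)n * Ci + ci) * H * W;
            double* wc = pdw + ((R_xlen_t)co * Ci + ci) * KH * KW;
            const double* wv = pw + ((R_xlen_t)co * Ci + ci) * KH * KW;
            double* xg = need_dx ? pdx + ((R_xlen_t)n * Ci + ci) * H * W : nullptr;
            for (int kw = kw_lo; kw < kw_hi; ++kw) {
              const double* xcol = xc + (R_xlen_t)(w0 + kw) * H + h0;
              double* wcol = wc + kw * KH;
              if (need_dx) {
                double* xgcol = xg + (R_xlen_t)(w0 + kw) * H + h0;
                const double* wvcol = wv + kw * KH;
                for (int kh = kh_lo; kh < kh_hi; ++kh) {
                  wcol[kh] += g * xcol[kh];
                  xgcol[kh] += g * wvcol[kh];
                }
              } else {
                for (int kh = kh_lo; kh < kh_hi; ++kh)
                  wcol[kh] += g * xcol[kh];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dxv : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}
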
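// Low-level numerical kernels for the convolutional network engine.
// All image/feature arrays use the R layout (h, w, channels, batch),
// column-major. Convolution weights are (kh, kw, c_in, c_out) so that a
// flat view is directly the (kh*kw*c_in) x c_out matrix used by im2col.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Allocator tuning for large-array workloads: the engine allocates and
// frees many multi-megabyte buffers per forward/backward pass. With
// glibc's default dynamic mmap threshold (capped at 32 MB) each goes
// through mmap/munmap and the kernel spends most of its time zeroing
// fresh pages; raising the thresholds keeps the buffers on the heap where
// they are recycled. Called from .onLoad.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Reusable scratch for im2col / gradient-column matrices: the backing
// buffers grow monotonically, so repeated convolutions of similar size do
// not re-fault fresh pages.
static arma::mat scratch_col(int slot, arma::uword nr, arma::uword nc) {
  static std::vector<double> buf[2];
  if (buf[slot].size() < nr * nc) buf[slot].resize(nr * nc);
  return arma::mat(buf[slot].data(), nr, nc, false, true);
}

static inline arma::uword off4(int i, int j, int c, int s, int h, int w, int cc) {
  return (arma::uword)i + (arma::uword)h * ((arma::uword)j + (arma::uword)w * ((arma::uword)c + (arma::uword)cc * (arma::uword)s));
}

// Build the im2col matrix (kh*kw*cin, oh*ow) for one sample.
static void im2col(const double* x, int h, int w, int cin, int s,
                   int kh, int kw, int stride, int pad,
                   int oh, int ow, arma::mat& col) {
  const double* xs = x + (arma::uword)h * w * cin * s;
  for (int ic = 0; ic < cin; ++ic) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ic);
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride + kj - pad;
          const bool jin = (j >= 0 && j < w);
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride + ki - pad;
            double v = 0.0;
            if (jin && i >= 0 && i < h)
              v = xs[(arma::uword)i + (arma::uword)h * (j + (arma::uword)w * ic)];
            col.at(r, oi + oh * oj) = v;
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the input grid (adjoint of im2col).
static void col2im(const arma::mat& col, double* gx, int h, int w, int cin, int s,
                   int kh, int kw, int stride, int pad, int oh, int ow) {
  double* gs = gx + (arma::uword)h * w * cin * s;
  for (int ic = 0; ic < cin; ++ic) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ic);
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= w) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= h) continue;
            gs[(arma::uword)i + (arma::uword)h * (j + (arma::uword)w * ic)] += col.at(r, oi + oh * oj);
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dim4(SEXP a) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(a, R_DimSymbol));
  if (d.size() != 4) stop("expected a 4-d array (h, w, c, n)");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wt, NumericVector b,
                            int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(wt);
  const int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  const int kh = dw[0], kw = dw[1], cout = dw[3];
  if (dw[2] != cin) stop("conv2d: input has %d channels but kernel expects %d", cin, dw[2]);
  const int oh = (h + 2 * pad - kh) / stride + 1;
  const int ow = (w + 2 * pad - kw) / stride + 1;
  if (oh <= 0 || ow <= 0) stop("conv2d: kernel larger than (padded) input");
  NumericVector y = alloc4(oh, ow, cout, n);
  const arma::uword L = (arma::uword)oh * ow;
  const arma::mat Wm(const_cast<double*>(wt.begin()), kh * kw * cin, cout, false, true);
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat ym = scratch_col(1, L * n, cout);
  if (one) {
    for (int s = 0; s < n; ++s) {
      const arma::mat Xs(const_cast<double*>(x.begin()) + (arma::uword)h * w * cin * s,
                         L, cin, false, true);
      ym.rows(L * s, L * s + L - 1) = Xs * Wm;
    }
  } else {
    arma::mat col = scratch_col(0, (arma::uword)kh * kw * cin, L * n);
    for (int s = 0; s < n; ++s) {
      arma::mat cs(col.memptr() + (arma::uword)kh * kw * cin * L * s,
                   kh * kw * cin, L, false, true);
      im2col(x.begin(), h, w, cin, s, kh, kw, stride, pad, oh, ow, cs);
    }
    ym = col.t() * Wm;
  }
  for (int s = 0; s < n; ++s) {
    double* ys = y.begin() + L * cout * s;
    for (int oc = 0; oc < cout; ++oc) {
      const double bb = b[oc];
      const double* src = ym.colptr(oc) + L * s;
      double* dst = ys + L * oc;
      for (arma::uword q = 0; q < L; ++q) dst[q] = src[q] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector wt, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(wt), dg = dim4(gy);
  const int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  const int kh = dw[0], kw = dw[1], cout = dw[3];
  const int oh = dg[0], ow = dg[1];
  const arma::uword L = (arma::uword)oh * ow;
  NumericVector gx = alloc4(h, w, cin, n);
  NumericVector gw = alloc4(kh, kw, cin, cout);
  NumericVector gb(cout);
  const arma::mat Wm(const_cast<double*>(wt.begin()), kh * kw * cin, cout, false, true);
  arma::mat gWm(gw.begin(), kh * kw * cin, cout, false, true);
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  // bias gradient and per-sample views of gy
  for (int s = 0; s < n; ++s) {
    const arma::mat gys(const_cast<double*>(gy.begin()) + L * cout * s,
                        L, cout, false, true);
    for (int oc = 0; oc < cout; ++oc) gb[oc] += arma::accu(gys.col(oc));
  }
  if (one) {
    for (int s = 0; s < n; ++s) {
      const arma::mat Xs(const_cast<double*>(x.begin()) + (arma::uword)h * w * cin * s,
                         L, cin, false, true);
      const arma::mat gys(const_cast<double*>(gy.begin()) + L * cout * s,
                          L, cout, false, true);
      gWm += Xs.t() * gys;
      arma::mat gXs(gx.begin() + (arma::uword)h * w * cin * s, L, cin, false, true);
      gXs = gys * Wm.t();
    }
  } else {
    arma::mat col = scratch_col(0, (arma::uword)kh * kw * cin, L * n);
    for (int s = 0; s < n; ++s) {
      arma::mat cs(col.memptr() + (arma::uword)kh * kw * cin * L * s,
                   kh * kw * cin, L, false, true);
      im2col(x.begin(), h, w, cin, s, kh, kw, stride, pad, oh, ow, cs);
    }
    arma::mat gcol = scratch_col(1, (arma::uword)kh * kw * cin, L * n);
    for (int s = 0; s < n; ++s) {
      const arma::mat gys(const_cast<double*>(gy.begin()) + L * cout * s,
                          L, cout, false, true);
      const arma::mat cs(col.memptr() + (arma::uword)kh * kw * cin * L * s,
                         kh * kw * cin, L, false, true);
      gWm += cs * gys;
      arma::mat gcs(gcol.memptr() + (arma::uword)kh * kw * cin * L * s,
                    kh * kw * cin, L, false, true);
      gcs = Wm * gys.t();
      col2im(gcs, gx.begin(), h, w, cin, s, kh, kw, stride, pad, oh, ow);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2, stride 2 (exact 2x upsampling).
// wt: (2, 2, cin, cout).
// [[Rcpp::export]]
NumericVector cpp_upconv2_fw(NumericVector x, NumericVector wt, NumericVector b) {
  IntegerVector dx = dim4(x), dw = dim4(wt);
  const int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  const int cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != cin) stop("upconv2: bad kernel shape");
  NumericVector y = alloc4(2 * h, 2 * w, cout, n);
  arma::mat Wab(cin, cout);
  for (int a = 0; a < 2; ++a) {
    for (int bb = 0; bb < 2; ++bb) {
      for (int oc = 0; oc < cout; ++oc)
        for (int ic = 0; ic < cin; ++ic)
          Wab.at(ic, oc) = wt[a + 2 * (bb + 2 * (ic + cin * oc))];
      for (int s = 0; s < n; ++s) {
        const arma::mat Xm(const_cast<double*>(x.begin()) + (arma::uword)h * w * cin * s,
                           h * w, cin, false, true);
        arma::mat ym = Xm * Wab;  // (h*w, cout)
        double* ys = y.begin() + (arma::uword)4 * h * w * cout * s;
        for (int oc = 0; oc < cout; ++oc) {
          const double* src = ym.colptr(oc);
          double* dst = ys + (arma::uword)4 * h * w * oc;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              dst[(arma::uword)(2 * i + a) + (arma::uword)2 * h * (2 * j + bb)] = src[i + (arma::uword)h * j] + b[oc];
        }
      }
    }
  }
  // each output position is covered by exactly one (a,b) tap, so the bias
  // added inside the scatter is added exactly once per pixel
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bw(NumericVector x, NumericVector wt, NumericVector gy) {
  IntegerVector dx = dim4(x), dw = dim4(wt);
  const int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  const int cout = dw[3];
  NumericVector gx = alloc4(h, w, cin, n);
  NumericVector gw = alloc4(2, 2, cin, cout);
  NumericVector gb(cout);
  arma::mat Wab(cin, cout), gWab(cin, cout);
  for (int a = 0; a < 2; ++a) {
    for (int bb = 0; bb < 2; ++bb) {
      for (int oc = 0; oc < cout; ++oc)
        for (int ic = 0; ic < cin; ++ic)
          Wab.at(ic, oc) = wt[a + 2 * (bb + 2 * (ic + cin * oc))];
      gWab.zeros();
      for (int s = 0; s < n; ++s) {
        const arma::mat Xm(const_cast<double*>(x.begin()) + (arma::uword)h * w * cin * s,
                           h * w, cin, false, true);
        arma::mat gYab(h * w, cout);
        const double* gys = gy.begin() + (arma::uword)4 * h * w * cout * s;
        for (int oc = 0; oc < cout; ++oc) {
          const double* src = gys + (arma::uword)4 * h * w * oc;
          double* dst = gYab.colptr(oc);
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              dst[i + (arma::uword)h * j] = src[(arma::uword)(2 * i + a) + (arma::uword)2 * h * (2 * j + bb)];
        }
        gWab += Xm.t() * gYab;
        arma::mat gXm = gYab * Wab.t();
        double* gxs = gx.begin() + (arma::uword)h * w * cin * s;
        for (int ic = 0; ic < cin; ++ic) {
          const double* src = gXm.colptr(ic);
          double* dst = gxs + (arma::uword)h * w * ic;
          for (int q = 0; q < h * w; ++q) dst[q] += src[q];
        }
      }
      for (int oc = 0; oc < cout; ++oc)
        for (int ic = 0; ic < cin; ++ic)
          gw[a + 2 * (bb + 2 * (ic + cin * oc))] = gWab.at(ic, oc);
    }
  }
  for (int s = 0; s < n; ++s) {
    const double* gys = gy.begin() + (arma::uword)4 * h * w * cout * s;
    for (int oc = 0; oc < cout; ++oc) {
      const double* src = gys + (arma::uword)4 * h * w * oc;
      double acc = 0.0;
      for (arma::uword q = 0; q < (arma::uword)4 * h * w; ++q) acc += src[q];
      gb[oc] += acc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  IntegerVector dx = dim4(x);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  if (h % 2 || w % 2) stop("avgpool2: height and width must be even");
  const int oh = h / 2, ow = w / 2;
  NumericVector y = alloc4(oh, ow, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = x.begin() + off4(0, 0, cc, s, h, w, c);
      double* ys = y.begin() + off4(0, 0, cc, s, oh, ow, c);
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          const int i = 2 * oi, j = 2 * oj;
          ys[oi + (arma::uword)oh * oj] = 0.25 * (xs[i + (arma::uword)h * j] + xs[i + 1 + (arma::uword)h * j] +
                                                  xs[i + (arma::uword)h * (j + 1)] + xs[i + 1 + (arma::uword)h * (j + 1)]);
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector gy, int h, int w) {
  IntegerVector dg = dim4(gy);
  const int oh = dg[0], ow = dg[1], c = dg[2], n = dg[3];
  NumericVector gx = alloc4(h, w, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* gs = gy.begin() + off4(0, 0, cc, s, oh, ow, c);
      double* xs = gx.begin() + off4(0, 0, cc, s, h, w, c);
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          const double g = 0.25 * gs[oi + (arma::uword)oh * oj];
          const int i = 2 * oi, j = 2 * oj;
          xs[i + (arma::uword)h * j] += g;
          xs[i + 1 + (arma::uword)h * j] += g;
          xs[i + (arma::uword)h * (j + 1)] += g;
          xs[i + 1 + (arma::uword)h * (j + 1)] += g;
        }
    }
  return gx;
}

// Apply per-position 3x3 kernel weights theta to zero-padded neighborhoods of x.
// theta channel layout: tap index t (0..8, t = di+1 + 3*(dj+1)) fastest, i.e.
// theta channel u = t + 9*c. Returns sum_t theta * shifted(x); the identity
// shortcut is added by the caller.
// [[Rcpp::export]]
NumericVector cpp_sekg_fw(NumericVector x, NumericVector theta) {
  IntegerVector dx = dim4(x), dt = dim4(theta);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  if (dt[2] != 9 * c || dt[0] != h || dt[1] != w || dt[3] != n)
    stop("sekg: theta must be (h, w, 9*c, n)");
  NumericVector y = alloc4(h, w, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = x.begin() + off4(0, 0, cc, s, h, w, c);
      double* ys = y.begin() + off4(0, 0, cc, s, h, w, c);
      for (int t = 0; t < 9; ++t) {
        const int di = t % 3 - 1, dj = t / 3 - 1;
        const double* ts = theta.begin() + off4(0, 0, t + 9 * cc, s, h, w, 9 * c);
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
        const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            ys[i + (arma::uword)h * j] += ts[i + (arma::uword)h * j] * xs[(i + di) + (arma::uword)h * (j + dj)];
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_sekg_bw(NumericVector x, NumericVector theta, NumericVector gy) {
  IntegerVector dx = dim4(x);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  NumericVector gx = alloc4(h, w, c, n);
  NumericVector gtheta = alloc4(h, w, 9 * c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = x.begin() + off4(0, 0, cc, s, h, w, c);
      double* gxs = gx.begin() + off4(0, 0, cc, s, h, w, c);
      const double* gys = gy.begin() + off4(0, 0, cc, s, h, w, c);
      for (int t = 0; t < 9; ++t) {
        const int di = t % 3 - 1, dj = t / 3 - 1;
        const double* ts = theta.begin() + off4(0, 0, t + 9 * cc, s, h, w, 9 * c);
        double* gts = gtheta.begin() + off4(0, 0, t + 9 * cc, s, h, w, 9 * c);
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
        const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i) {
            const double g = gys[i + (arma::uword)h * j];
            gts[i + (arma::uword)h * j] = g * xs[(i + di) + (arma::uword)h * (j + dj)];
            gxs[(i + di) + (arma::uword)h * (j + dj)] += g * ts[i + (arma::uword)h * j];
          }
      }
    }
  return List::create(_["gx"] = gx, _["gtheta"] = gtheta);
}

// Depthwise 3x3 convolution (stride 1, zero padding 1), one kernel per channel.
// wt: (3, 3, c); used by the SEKG spatial branch.
// [[Rcpp::export]]
NumericVector cpp_dwconv3_fw(NumericVector x, NumericVector wt, NumericVector b) {
  IntegerVector dx = dim4(x);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  NumericVector y = alloc4(h, w, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = x.begin() + off4(0, 0, cc, s, h, w, c);
      double* ys = y.begin() + off4(0, 0, cc, s, h, w, c);
      const double* k = wt.begin() + 9 * cc;
      const double bb = b[cc];
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double acc = bb;
          for (int kj = 0; kj < 3; ++kj) {
            const int jj = j + kj - 1;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < 3; ++ki) {
              const int ii = i + ki - 1;
              if (ii < 0 || ii >= h) continue;
              acc += k[ki + 3 * kj] * xs[ii + (arma::uword)h * jj];
            }
          }
          ys[i + (arma::uword)h * j] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3_bw(NumericVector x, NumericVector wt, NumericVector gy) {
  IntegerVector dx = dim4(x);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  NumericVector gx = alloc4(h, w, c, n);
  NumericVector gw(Dimension(3, 3, c));
  NumericVector gb(c);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = x.begin() + off4(0, 0, cc, s, h, w, c);
      double* gxs = gx.begin() + off4(0, 0, cc, s, h, w, c);
      const double* gys = gy.begin() + off4(0, 0, cc, s, h, w, c);
      const double* k = wt.begin() + 9 * cc;
      double* gk = gw.begin() + 9 * cc;
      double gbb = 0.0;
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          const double g = gys[i + (arma::uword)h * j];
          gbb += g;
          for (int kj = 0; kj < 3; ++kj) {
            const int jj = j + kj - 1;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < 3; ++ki) {
              const int ii = i + ki - 1;
              if (ii < 0 || ii >= h) continue;
              gk[ki + 3 * kj] += g * xs[ii + (arma::uword)h * jj];
              gxs[ii + (arma::uword)h * jj] += g * k[ki + 3 * kj];
            }
          }
        }
      gb[cc] += gbb;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- elementwise / broadcast helpers (hot paths of the tape) -------------

// [[Rcpp::export]]
NumericVector cpp_prelu_fw(NumericVector x, double a) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t nn = x.size();
  for (R_xlen_t i = 0; i < nn; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : a * xp[i];
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_bw(NumericVector x, double a, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  double ga = 0.0;
  const R_xlen_t nn = x.size();
  for (R_xlen_t i = 0; i < nn; ++i) {
    if (xp[i] > 0) op[i] = gp[i];
    else { op[i] = a * gp[i]; ga += gp[i] * xp[i]; }
  }
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t nn = x.size();
  for (R_xlen_t i = 0; i < nn; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return y;
}

// x (h, w, c, n) op v (1, 1, c, n); mode 0 = add, 1 = multiply
// [[Rcpp::export]]
NumericVector cpp_bcast_fw(NumericVector x, NumericVector v, int mode) {
  IntegerVector dx = dim4(x);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  const arma::uword hw = (arma::uword)h * w;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double vv = v[cc + (arma::uword)c * s];
      const double* xp = x.begin() + hw * (cc + (arma::uword)c * s);
      double* yp = y.begin() + hw * (cc + (arma::uword)c * s);
      if (mode == 0) for (arma::uword q = 0; q < hw; ++q) yp[q] = xp[q] + vv;
      else for (arma::uword q = 0; q < hw; ++q) yp[q] = xp[q] * vv;
    }
  return y;
}

// channelwise sums of g (h, w, c, n) -> (1, 1, c, n)
// [[Rcpp::export]]
NumericVector cpp_chan_sum(NumericVector g) {
  IntegerVector dg = dim4(g);
  const int h = dg[0], w = dg[1], c = dg[2], n = dg[3];
  const arma::uword hw = (arma::uword)h * w;
  NumericVector out((R_xlen_t)c * n);
  out.attr("dim") = IntegerVector::create(1, 1, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* gp = g.begin() + hw * (cc + (arma::uword)c * s);
      double acc = 0.0;
      for (arma::uword q = 0; q < hw; ++q) acc += gp[q];
      out[cc + (arma::uword)c * s] = acc;
    }
  return out;
}

// g (h, w, c, n) times x (h, w, c, n), summed per channel -> (1, 1, c, n)
// [[Rcpp::export]]
NumericVector cpp_chan_dot(NumericVector g, NumericVector x) {
  IntegerVector dg = dim4(g);
  const int h = dg[0], w = dg[1], c = dg[2], n = dg[3];
  const arma::uword hw = (arma::uword)h * w;
  NumericVector out((R_xlen_t)c * n);
  out.attr("dim") = IntegerVector::create(1, 1, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* gp = g.begin() + hw * (cc + (arma::uword)c * s);
      const double* xp = x.begin() + hw * (cc + (arma::uword)c * s);
      double acc = 0.0;
      for (arma::uword q = 0; q < hw; ++q) acc += gp[q] * xp[q];
      out[cc + (arma::uword)c * s] = acc;
    }
  return out;
}

// broadcast (1, 1, c, n) values uniformly over (h, w) -> (h, w, c, n), scaled
// [[Rcpp::export]]
NumericVector cpp_chan_spread(NumericVector v, int h, int w, double scale) {
  IntegerVector dv = dim4(v);
  const int c = dv[2], n = dv[3];
  const arma::uword hw = (arma::uword)h * w;
  NumericVector y((R_xlen_t)hw * c * n);
  y.attr("dim") = IntegerVector::create(h, w, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double vv = v[cc + (arma::uword)c * s] * scale;
      double* yp = y.begin() + hw * (cc + (arma::uword)c * s);
      for (arma::uword q = 0; q < hw; ++q) yp[q] = vv;
    }
  return y;
}
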
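// 3D convolution kernels for the segmentation network.
//
// Feature maps are single-sample dense arrays with dim (Z, Y, X, C),
// column-major (z fastest).  Convolution weights for a k^3 kernel have dim
// (k, k, k, Cin, Cout).  The im2col patch matrix is built slab-by-slab
// along x so its memory footprint stays bounded, and the contraction runs
// through BLAS gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reusable im2col workspace (grown on demand, avoids repeated large
// allocations and their page-fault zeroing cost).  The patch matrix and
// gemm run in single precision: the contraction is short (<= 1000 terms)
// and weights/activations are O(1), so float keeps ~6 significant digits
// while halving memory traffic.
static std::vector<float>& workspace(size_t n) {
  static std::vector<float> buf;
  if (buf.size() < n) buf.resize(n);
  return buf;
}

static inline IntegerVector dims_of(const NumericVector& a, int need) {
  IntegerVector d = a.attr("dim");
  if (d.size() != need) stop("array with %d dims expected", need);
  return d;
}

// Fill the patch matrix P (Nslab x K) for output x-range [x0, x1).
// K = k^3 * Cin, column index = dz + k*dy + k^2*dx + k^3*c.  Column-major
// storage makes each (offset, channel) fill a contiguous shifted copy of
// the source volume, which keeps the fill memory-bandwidth bound.
static void im2col_slab(const double* x, int Z, int Y, int X, int C,
                        int k, int pad, int x0, int x1, arma::fmat& P) {
  const int nxs = x1 - x0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)Z * Y * X * c;
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy)
        for (int dz = 0; dz < k; ++dz) {
          const size_t col = dz + (size_t)k * dy + (size_t)k * k * dx +
                             (size_t)k * k * k * c;
          float* dst0 = P.colptr(col);
          const int zlo = std::max(0, pad - dz);
          const int zhi = std::min(Z - 1, Z - 1 + pad - dz);
          for (int xs = 0; xs < nxs; ++xs) {
            const int xi = x0 + xs + dx - pad;
            for (int y = 0; y < Y; ++y) {
              float* dst = dst0 + (size_t)Z * (y + (size_t)Y * xs);
              const int yi = y + dy - pad;
              if (xi < 0 || xi >= X || yi < 0 || yi >= Y) {
                std::fill(dst, dst + Z, 0.0f);
                continue;
              }
              const double* src = xc + (size_t)Z * (yi + (size_t)Y * xi) +
                                  dz - pad;
              if (zlo > 0) std::fill(dst, dst + zlo, 0.0f);
              for (int z = zlo; z <= zhi; ++z) dst[z] = (float)src[z];
              if (zhi < Z - 1) std::fill(dst + zhi + 1, dst + Z, 0.0f);
            }
          }
        }
  }
}

static int slab_width(int Z, int Y, int X, int K) {
  // keep the patch matrix near 64 MB
  double per_x = (double)K * Z * Y * 8.0;
  int w = (int)std::floor(64.0 * 1024 * 1024 / std::max(per_x, 1.0));
  return std::max(1, std::min(X, w));
}

// Direct shift-accumulate convolution: cheaper than im2col + gemm when
// there are very few input channels (the 7^3 spatial-attention kernel).
static NumericVector conv3d_direct(NumericVector x, NumericVector w,
                                   NumericVector b, int Z, int Y, int X,
                                   int Cin, int Cout, int k, int pad) {
  const size_t N = (size_t)Z * Y * X;
  NumericVector out(N * Cout);
  out.attr("dim") = IntegerVector::create(Z, Y, X, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* oc = out.begin() + N * co;
    for (size_t i = 0; i < N; ++i) oc[i] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + N * ci;
      for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy)
      for (int dz = 0; dz < k; ++dz) {
        const double wv = w[dz + (size_t)k * dy + (size_t)k * k * dx +
                            (size_t)k * k * k * ci +
                            (size_t)k * k * k * Cin * co];
        if (wv == 0.0) continue;
        const int oz = dz - pad, oy = dy - pad, ox = dx - pad;
        const int zlo = std::max(0, -oz), zhi = std::min(Z, Z - oz);
        for (int xx = std::max(0, -ox); xx < std::min(X, X - ox); ++xx)
        for (int yy = std::max(0, -oy); yy < std::min(Y, Y - oy); ++yy) {
          double* dst = oc + (size_t)Z * (yy + (size_t)Y * xx);
          const double* src = xc + (size_t)Z * ((yy + oy) + (size_t)Y * (xx + ox)) + oz;
          for (int zz = zlo; zz < zhi; ++zz) dst[zz] += wv * src[zz];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         bool relu = false) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5);
  const int Z = xd[0], Y = xd[1], X = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (wd[1] != k || wd[2] != k) stop("kernel must be cubic");
  if (Cin != C) stop("input channels (%d) do not match kernel (%d)", C, Cin);
  const int pad = (k - 1) / 2;
  if ((size_t)Cin * Cout <= 4) {
    NumericVector out = conv3d_direct(x, w, b, Z, Y, X, Cin, Cout, k, pad);
    if (relu)
      for (R_xlen_t i = 0; i < out.size(); ++i)
        if (out[i] < 0) out[i] = 0;
    return out;
  }
  const int K = k * k * k * Cin;
  const size_t N = (size_t)Z * Y * X;

  NumericVector out(N * Cout);
  out.attr("dim") = IntegerVector::create(Z, Y, X, Cout);
  arma::fmat W(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) W[i] = (float)w[i];

  const int sw = slab_width(Z, Y, X, K);
  std::vector<float>& buf = workspace((size_t)Z * Y * sw * K);
  for (int x0 = 0; x0 < X; x0 += sw) {
    const int x1 = std::min(X, x0 + sw);
    const size_t Ns = (size_t)Z * Y * (x1 - x0);
    arma::fmat Psub(buf.data(), Ns, K, false, true);
    im2col_slab(x.begin(), Z, Y, X, C, k, pad, x0, x1, Psub);
    arma::fmat O = Psub * W;  // Ns x Cout
    for (int co = 0; co < Cout; ++co) {
      double* dst = out.begin() + (size_t)Z * Y * x0 + N * co;
      const float* src = O.colptr(co);
      const double bias = b[co];
      if (relu)
        for (size_t i = 0; i < Ns; ++i)
          dst[i] = std::max(0.0, src[i] + bias);
      else
        for (size_t i = 0; i < Ns; ++i) dst[i] = src[i] + bias;
    }
  }
  return out;
}

// Gradients w.r.t. weights and bias; dX is computed in R by calling
// conv3d_fwd with spatially flipped, channel-transposed weights.
// [[Rcpp::export]]
List conv3d_bwd_w(NumericVector x, NumericVector dy, int k) {
  IntegerVector xd = dims_of(x, 4), yd = dims_of(dy, 4);
  const int Z = xd[0], Y = xd[1], X = xd[2], Cin = xd[3];
  const int Cout = yd[3];
  if (yd[0] != Z || yd[1] != Y || yd[2] != X) stop("shape mismatch");
  const int pad = (k - 1) / 2;
  const int K = k * k * k * Cin;
  const size_t N = (size_t)Z * Y * X;

  arma::fmat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  const int sw = slab_width(Z, Y, X, K);
  std::vector<float>& buf = workspace((size_t)Z * Y * sw * K);
  arma::fmat dYs;
  for (int x0 = 0; x0 < X; x0 += sw) {
    const int x1 = std::min(X, x0 + sw);
    const size_t Ns = (size_t)Z * Y * (x1 - x0);
    arma::fmat Psub(buf.data(), Ns, K, false, true);
    im2col_slab(x.begin(), Z, Y, X, Cin, k, pad, x0, x1, Psub);
    dYs.set_size(Ns, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + (size_t)Z * Y * x0 + N * co;
      float* dst = dYs.colptr(co);
      double s = 0.0;
      for (size_t i = 0; i < Ns; ++i) { dst[i] = (float)src[i]; s += src[i]; }
      db[co] += s;
    }
    dW += Psub.t() * dYs;
  }

  NumericVector dw(dW.begin(), dW.end());
  dw.attr("dim") = IntegerVector::create(k, k, k, Cin, Cout);
  return List::create(_["dw"] = dw, _["db"] = NumericVector(db.begin(), db.end()));
}

// Stride-2, kernel-2 transposed convolution (doubles each spatial dim).
// [[Rcpp::export]]
NumericVector tconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5);
  const int Z = xd[0], Y = xd[1], X = xd[2], Cin = xd[3];
  const int Cout = wd[4];
  if (wd[0] != 2 || wd[3] != Cin) stop("bad tconv weights");
  const int Z2 = 2 * Z, Y2 = 2 * Y, X2 = 2 * X;
  const size_t N2 = (size_t)Z2 * Y2 * X2;
  NumericVector out(N2 * Cout);
  out.attr("dim") = IntegerVector::create(Z2, Y2, X2, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* oc = out.begin() + N2 * co;
    for (size_t i = 0; i < N2; ++i) oc[i] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + (size_t)Z * Y * X * ci;
      for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz) {
        const double wv =
            w[dz + 2 * dy + 4 * dx + 8 * ci + 8 * (size_t)Cin * co];
        for (int xx = 0; xx < X; ++xx)
        for (int yy = 0; yy < Y; ++yy) {
          const double* src = xc + (size_t)Z * (yy + (size_t)Y * xx);
          double* dst = oc + (size_t)(2 * xx + dx) * Z2 * Y2 +
                        (size_t)(2 * yy + dy) * Z2 + dz;
          for (int zz = 0; zz < Z; ++zz) dst[2 * zz] += wv * src[zz];
        }
      }
    }
  }
  return out;
}

// Full backward for tconv2 including dX (needs the weights).
// [[Rcpp::export]]
List tconv2_bwd_full(NumericVector x, NumericVector dy, NumericVector w) {
  IntegerVector xd = dims_of(x, 4), yd = dims_of(dy, 4), wd = dims_of(w, 5);
  const int Z = xd[0], Y = xd[1], X = xd[2], Cin = xd[3];
  const int Cout = wd[4];
  const int Z2 = yd[0], Y2 = yd[1], X2 = yd[2];
  if (Z2 != 2 * Z || Y2 != 2 * Y || X2 != 2 * X || yd[3] != Cout)
    stop("shape mismatch");
  const size_t N = (size_t)Z * Y * X, N2 = (size_t)Z2 * Y2 * X2;

  NumericVector dx(N * Cin), dw((size_t)8 * Cin * Cout), db(Cout);
  dx.attr("dim") = IntegerVector::create(Z, Y, X, Cin);
  dw.attr("dim") = IntegerVector::create(2, 2, 2, Cin, Cout);

  for (int co = 0; co < Cout; ++co) {
    const double* gc = dy.begin() + N2 * co;
    double s = 0.0;
    for (size_t i = 0; i < N2; ++i) s += gc[i];
    db[co] += s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + N * ci;
      double* dxc = dx.begin() + N * ci;
      for (int dxo = 0; dxo < 2; ++dxo)
      for (int dyo = 0; dyo < 2; ++dyo)
      for (int dzo = 0; dzo < 2; ++dzo) {
        const size_t widx = dzo + 2 * dyo + 4 * dxo + 8 * (size_t)ci +
                            8 * (size_t)Cin * co;
        const double wv = w[widx];
        double wg = 0.0;
        for (int xx = 0; xx < X; ++xx)
        for (int yy = 0; yy < Y; ++yy) {
          const double* xs = xc + (size_t)Z * (yy + (size_t)Y * xx);
          double* dxs = dxc + (size_t)Z * (yy + (size_t)Y * xx);
          const double* gs = gc + (size_t)(2 * xx + dxo) * Z2 * Y2 +
                             (size_t)(2 * yy + dyo) * Z2 + dzo;
          for (int zz = 0; zz < Z; ++zz) {
            wg += xs[zz] * gs[2 * zz];
            dxs[zz] += wv * gs[2 * zz];
          }
        }
        dw[widx] += wg;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Block-mean pooling by integer factors; trailing partial cells average
// over the voxels actually present.
// [[Rcpp::export]]
NumericVector pool_mean_fwd(NumericVector x, IntegerVector f) {
  IntegerVector xd = dims_of(x, 4);
  const int Z = xd[0], Y = xd[1], X = xd[2], C = xd[3];
  const int fz = f[0], fy = f[1], fx = f[2];
  const int Zo = (Z + fz - 1) / fz, Yo = (Y + fy - 1) / fy,
            Xo = (X + fx - 1) / fx;
  const size_t No = (size_t)Zo * Yo * Xo;
  NumericVector out(No * C);
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)Z * Y * X * c;
    double* oc = out.begin() + No * c;
    for (int xo = 0; xo < Xo; ++xo)
    for (int yo = 0; yo < Yo; ++yo)
    for (int zo = 0; zo < Zo; ++zo) {
      double s = 0.0;
      int n = 0;
      for (int xx = xo * fx; xx < std::min(X, (xo + 1) * fx); ++xx)
      for (int yy = yo * fy; yy < std::min(Y, (yo + 1) * fy); ++yy)
      for (int zz = zo * fz; zz < std::min(Z, (zo + 1) * fz); ++zz) {
        s += xc[zz + (size_t)Z * (yy + (size_t)Y * xx)];
        ++n;
      }
      oc[zo + (size_t)Zo * (yo + (size_t)Yo * xo)] = s / n;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector pool_mean_bwd(NumericVector dy, IntegerVector xdim,
                            IntegerVector f) {
  const int Z = xdim[0], Y = xdim[1], X = xdim[2], C = xdim[3];
  const int fz = f[0], fy = f[1], fx = f[2];
  IntegerVector yd = dims_of(dy, 4);
  const int Zo = yd[0], Yo = yd[1], Xo = yd[2];
  const size_t N = (size_t)Z * Y * X, No = (size_t)Zo * Yo * Xo;
  NumericVector dx(N * C);
  dx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = dy.begin() + No * c;
    double* dc = dx.begin() + N * c;
    for (int xo = 0; xo < Xo; ++xo)
    for (int yo = 0; yo < Yo; ++yo)
    for (int zo = 0; zo < Zo; ++zo) {
      const int x1 = std::min(X, (xo + 1) * fx), y1 = std::min(Y, (yo + 1) * fy),
                z1 = std::min(Z, (zo + 1) * fz);
      const int n = (x1 - xo * fx) * (y1 - yo * fy) * (z1 - zo * fz);
      const double g = gc[zo + (size_t)Zo * (yo + (size_t)Yo * xo)] / n;
      for (int xx = xo * fx; xx < x1; ++xx)
      for (int yy = yo * fy; yy < y1; ++yy)
      for (int zz = zo * fz; zz < z1; ++zz)
        dc[zz + (size_t)Z * (yy + (size_t)Y * xx)] += g;
    }
  }
  return dx;
}

// y = max(x, 0), preserving dims
// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// dy masked by (act > 0); act is the post-ReLU activation
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dy, NumericVector act) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = act[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// y = x %*% w + b (and optional ReLU) for 1x1x1 convolutions; x is the
// (N x Cin) matrix view of a feature map
// [[Rcpp::export]]
NumericVector conv1x1_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                          bool relu = false) {
  IntegerVector xd = dims_of(x, 4);
  const size_t N = (size_t)xd[0] * xd[1] * xd[2];
  const int Cin = xd[3], Cout = w.ncol();
  if (w.nrow() != Cin) stop("conv1x1 weight shape mismatch");
  NumericVector out(N * Cout);
  out.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], Cout);
  arma::mat X(const_cast<double*>(x.begin()), N, Cin, false, true);
  arma::mat W(const_cast<double*>(w.begin()), Cin, Cout, false, true);
  arma::mat O(out.begin(), N, Cout, false, true);
  O = X * W;
  for (int co = 0; co < Cout; ++co) {
    double* oc = out.begin() + N * co;
    const double bias = b[co];
    if (relu)
      for (size_t i = 0; i < N; ++i) oc[i] = std::max(0.0, oc[i] + bias);
    else
      for (size_t i = 0; i < N; ++i) oc[i] += bias;
  }
  return out;
}

// columnwise scale of an (N x C) feature map: out[, c] = x[, c] * a[c]
// [[Rcpp::export]]
NumericVector scale_cols(NumericVector x, NumericVector a) {
  IntegerVector xd = dims_of(x, 4);
  const size_t N = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector out(N * C);
  out.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    double* oc = out.begin() + N * c;
    const double s = a[c];
    for (size_t i = 0; i < N; ++i) oc[i] = xc[i] * s;
  }
  return out;
}

// elementwise a * b (same length), preserving a's dims
// [[Rcpp::export]]
NumericVector mul_elem(NumericVector a, NumericVector b) {
  NumericVector out(a.size());
  out.attr("dim") = a.attr("dim");
  for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = a[i] * b[i];
  return out;
}

// in-place variant: overwrites dy where the activation was clipped.  Only
// safe when dy is a temporary whose sole binding is rebound to the result.
// [[Rcpp::export]]
NumericVector relu_bwd_inplace(NumericVector dy, NumericVector act) {
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (act[i] <= 0) dy[i] = 0.0;
  return dy;
}
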
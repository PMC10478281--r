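// Low-level kernels for the conv-net engine and the differentiable warp.
//
// Array conventions (all column-major R arrays):
//   image / feature map : dim (H, W, C)
//   conv kernel         : dim (kh, kw, C_in, C_out)
//   displacement field  : dim (H, W, 2), [,,1] = row offset, [,,2] = col offset
//
// Convolutions are lowered to GEMM via im2col; gradients use the adjoint
// col2im scatter. Transposed convolution is the adjoint of a stride-s
// convolution whose kernel is stored as dim (kh, kw, C_out, C_in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// column r = a + kh*(b + kw*c) of `cols` holds input value at kernel offset
// (a, b), channel c, for each output position (io, jo) (zero padding).
static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  arma::mat cols(kh * kw * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride + b - pad;
          if (j < 0 || j >= W) continue;
          const double* xcol = xc + (size_t)H * j;
          double* crow = cols.memptr() + r;
          for (int io = 0; io < Ho; ++io) {
            int i = io * stride + a - pad;
            if (i < 0 || i >= H) continue;
            crow[(size_t)(io + (size_t)Ho * jo) * cols.n_rows] = xcol[i];
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add columns back onto an (H, W, C) image
static void col2im(const arma::mat& cols, double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride + b - pad;
          if (j < 0 || j >= W) continue;
          double* xcol = xc + (size_t)H * j;
          for (int io = 0; io < Ho; ++io) {
            int i = io * stride + a - pad;
            if (i < 0 || i >= H) continue;
            xcol[i] += cols(r, io + (size_t)Ho * jo);
          }
        }
      }
    }
  }
}

static void get_dims3(const NumericVector& x, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d (H, W, C) array");
  H = d[0]; W = d[1]; C = d[2];
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (H + 2 * pad < kh || W + 2 * pad < kw || Ho < 1 || Wo < 1)
    stop("input (%d x %d) too small for %d x %d kernel", H, W, kh, kw);
  arma::mat cols = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat y = cols.t() * Wm;  // (Ho*Wo) x Cout
  for (int co = 0; co < Cout; ++co) y.col(co) += b[co];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  int H, W, C; get_dims3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  arma::mat cols = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat Gy(const_cast<double*>(gy.begin()), (size_t)Ho * Wo, Cout, false, true);
  arma::mat gW = cols * Gy;            // (kh*kw*C) x Cout
  arma::rowvec gb = arma::sum(Gy, 0);
  arma::mat gcols = Wm * Gy.t();       // (kh*kw*C) x (Ho*Wo)
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  col2im(gcols, gx.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gW"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed convolution: z (Ho, Wo, Cout) such that a stride-s conv of z
// with kernel w (kh, kw, Cout, Cin) yields x's spatial shape (h, w, Cin).
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int Ho, int Wo) {
  int h, wd_, Cin; get_dims3(x, h, wd_, Cin);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cout = wd[2], Cin_w = wd[3];
  if (Cin_w != Cin) stop("channel mismatch in transposed convolution");
  if ((Ho + 2 * pad - kh) / stride + 1 != h ||
      (Wo + 2 * pad - kw) / stride + 1 != wd_)
    stop("inconsistent transposed-convolution output size");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cout, Cin, false, true);
  arma::mat X(const_cast<double*>(x.begin()), (size_t)h * wd_, Cin, false, true);
  arma::mat gcols = Wm * X.t();  // (kh*kw*Cout) x (h*w)
  NumericVector z((size_t)Ho * Wo * Cout);
  z.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  col2im(gcols, z.begin(), Ho, Wo, Cout, kh, kw, stride, pad, h, wd_);
  double* zp = z.begin();
  for (int co = 0; co < Cout; ++co) {
    double bc = b[co];
    double* zc = zp + (size_t)Ho * Wo * co;
    for (size_t k = 0; k < (size_t)Ho * Wo; ++k) zc[k] += bc;
  }
  return z;
}

// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericVector w, NumericVector gz,
                   int stride, int pad) {
  // x: input of convT (h, w, Cin); gz: gradient at output (Ho, Wo, Cout)
  int h, wd_, Cin; get_dims3(x, h, wd_, Cin);
  int Ho, Wo, Cout; get_dims3(gz, Ho, Wo, Cout);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1];
  // g wrt x = forward conv of gz with w ((kh,kw,Cout,Cin) read as conv kernel)
  arma::mat cols = im2col(gz.begin(), Ho, Wo, Cout, kh, kw, stride, pad, h, wd_);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cout, Cin, false, true);
  arma::mat GX = cols.t() * Wm;  // (h*w) x Cin
  NumericVector gx(GX.begin(), GX.end());
  gx.attr("dim") = x.attr("dim");
  // g wrt w: same bilinear form as conv weight grad with roles (gz, x)
  arma::mat X(const_cast<double*>(x.begin()), (size_t)h * wd_, Cin, false, true);
  arma::mat gW = cols * X;  // (kh*kw*Cout) x Cin
  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = w.attr("dim");
  // g wrt b: sum of gz per output channel
  NumericVector gb(Cout);
  const double* gzp = gz.begin();
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    const double* gc = gzp + (size_t)Ho * Wo * co;
    for (size_t k = 0; k < (size_t)Ho * Wo; ++k) s += gc[k];
    gb[co] = s;
  }
  return List::create(_["gx"] = gx, _["gW"] = gWout, _["gb"] = gb);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear warp: out(i,j,c) = img sampled at (i + f1(i,j), j + f2(i,j)),
// sample coordinates clamped to the image border.
// [[Rcpp::export]]
NumericVector cpp_warp_fwd(NumericVector img, NumericVector field) {
  int H, W, C; get_dims3(img, H, W, C);
  int Hf, Wf, Cf; get_dims3(field, Hf, Wf, Cf);
  if (Hf != H || Wf != W || Cf != 2)
    stop("field must be (H, W, 2) matching the image grid");
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = img.attr("dim");
  const double* f1 = field.begin();
  const double* f2 = field.begin() + (size_t)H * W;
  const double* ip = img.begin();
  double* op = out.begin();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t p = i + (size_t)H * j;
      double si = clampd(i + f1[p], 0.0, H - 1.0);
      double sj = clampd(j + f2[p], 0.0, W - 1.0);
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      if (i0 > H - 2) i0 = H - 2; if (i0 < 0) i0 = 0;
      if (j0 > W - 2) j0 = W - 2; if (j0 < 0) j0 = 0;
      int i1 = H > 1 ? i0 + 1 : 0, j1 = W > 1 ? j0 + 1 : 0;
      double wi = si - i0, wj = sj - j0;
      for (int c = 0; c < C; ++c) {
        const double* ic = ip + (size_t)H * W * c;
        double v00 = ic[i0 + (size_t)H * j0], v10 = ic[i1 + (size_t)H * j0];
        double v01 = ic[i0 + (size_t)H * j1], v11 = ic[i1 + (size_t)H * j1];
        op[p + (size_t)H * W * c] =
          (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
          (1 - wi) * wj * v01 + wi * wj * v11;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_warp_bwd(NumericVector img, NumericVector field, NumericVector gy) {
  int H, W, C; get_dims3(img, H, W, C);
  NumericVector gimg((size_t)H * W * C);
  gimg.attr("dim") = img.attr("dim");
  NumericVector gfield((size_t)H * W * 2);
  gfield.attr("dim") = field.attr("dim");
  const double* f1 = field.begin();
  const double* f2 = field.begin() + (size_t)H * W;
  const double* ip = img.begin();
  const double* gp = gy.begin();
  double* gi = gimg.begin();
  double* g1 = gfield.begin();
  double* g2 = gfield.begin() + (size_t)H * W;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t p = i + (size_t)H * j;
      double si_raw = i + f1[p], sj_raw = j + f2[p];
      double si = clampd(si_raw, 0.0, H - 1.0);
      double sj = clampd(sj_raw, 0.0, W - 1.0);
      bool free_i = si_raw > 0.0 && si_raw < H - 1.0;
      bool free_j = sj_raw > 0.0 && sj_raw < W - 1.0;
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      if (i0 > H - 2) i0 = H - 2; if (i0 < 0) i0 = 0;
      if (j0 > W - 2) j0 = W - 2; if (j0 < 0) j0 = 0;
      int i1 = H > 1 ? i0 + 1 : 0, j1 = W > 1 ? j0 + 1 : 0;
      double wi = si - i0, wj = sj - j0;
      double gsi = 0.0, gsj = 0.0;
      for (int c = 0; c < C; ++c) {
        const double* ic = ip + (size_t)H * W * c;
        double* gc = gi + (size_t)H * W * c;
        double g = gp[p + (size_t)H * W * c];
        double v00 = ic[i0 + (size_t)H * j0], v10 = ic[i1 + (size_t)H * j0];
        double v01 = ic[i0 + (size_t)H * j1], v11 = ic[i1 + (size_t)H * j1];
        gc[i0 + (size_t)H * j0] += g * (1 - wi) * (1 - wj);
        gc[i1 + (size_t)H * j0] += g * wi * (1 - wj);
        gc[i0 + (size_t)H * j1] += g * (1 - wi) * wj;
        gc[i1 + (size_t)H * j1] += g * wi * wj;
        gsi += g * ((1 - wj) * (v10 - v00) + wj * (v11 - v01));
        gsj += g * ((1 - wi) * (v01 - v00) + wi * (v11 - v10));
      }
      g1[p] = free_i ? gsi : 0.0;
      g2[p] = free_j ? gsj : 0.0;
    }
  }
  return List::create(_["gimg"] = gimg, _["gfield"] = gfield);
}
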
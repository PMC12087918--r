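// 3D convolution and max-pooling kernels (forward + backward) used by the
// residual feature encoder. Arrays are column-major with layout
// (channels, depth, height, width, batch); convolution is im2col + GEMM.
// Kernel size, stride and padding are per axis, so axes that have collapsed
// to size 1 can use a length-1 kernel instead of wasting taps on padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x, int ndim,
                                    const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != ndim) stop("%s must have %d dimensions", what, ndim);
  return d;
}

static inline int out_size(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

struct ConvGeom {
  int C, D, H, W;
  int Kd, Kh, Kw;
  int pd, ph, pw;
  int sd, sh, sw;
  int Do, Ho, Wo;
  int rows() const { return C * Kd * Kh * Kw; }
  int cols() const { return Do * Ho * Wo; }
};

// Fill the im2col patch matrix for one sample.
// P has C*Kd*Kh*Kw rows (channel fastest, then kd, kh, kw) and Do*Ho*Wo
// columns (od fastest, then oh, ow).
static void im2col(const double* x, const ConvGeom& g, arma::mat& P) {
  P.zeros();
  const int DH = g.D * g.H;
  for (int ow = 0; ow < g.Wo; ++ow) {
    for (int oh = 0; oh < g.Ho; ++oh) {
      for (int od = 0; od < g.Do; ++od) {
        const int col = od + g.Do * (oh + g.Ho * ow);
        double* pcol = P.colptr(col);
        for (int kw = 0; kw < g.Kw; ++kw) {
          const int w = ow * g.sw - g.pw + kw;
          if (w < 0 || w >= g.W) continue;
          for (int kh = 0; kh < g.Kh; ++kh) {
            const int h = oh * g.sh - g.ph + kh;
            if (h < 0 || h >= g.H) continue;
            for (int kd = 0; kd < g.Kd; ++kd) {
              const int d = od * g.sd - g.pd + kd;
              if (d < 0 || d >= g.D) continue;
              const double* src = x + g.C * (d + g.D * h + DH * w);
              double* dst = pcol + g.C * (kd + g.Kd * (kh + g.Kh * kw));
              std::copy(src, src + g.C, dst);
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-matrix gradient back onto the input gradient
// (inverse of im2col).
static void col2im_add(const arma::mat& dP, const ConvGeom& g, double* dx) {
  const int DH = g.D * g.H;
  for (int ow = 0; ow < g.Wo; ++ow) {
    for (int oh = 0; oh < g.Ho; ++oh) {
      for (int od = 0; od < g.Do; ++od) {
        const int col = od + g.Do * (oh + g.Ho * ow);
        const double* pcol = dP.colptr(col);
        for (int kw = 0; kw < g.Kw; ++kw) {
          const int w = ow * g.sw - g.pw + kw;
          if (w < 0 || w >= g.W) continue;
          for (int kh = 0; kh < g.Kh; ++kh) {
            const int h = oh * g.sh - g.ph + kh;
            if (h < 0 || h >= g.H) continue;
            for (int kd = 0; kd < g.Kd; ++kd) {
              const int d = od * g.sd - g.pd + kd;
              if (d < 0 || d >= g.D) continue;
              double* dst = dx + g.C * (d + g.D * h + DH * w);
              const double* src = pcol + g.C * (kd + g.Kd * (kh + g.Kh * kw));
              for (int c = 0; c < g.C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

static ConvGeom make_geom(const IntegerVector& xd, const IntegerVector& wd,
                          const IntegerVector& stride,
                          const IntegerVector& pad) {
  if (stride.size() != 3 || pad.size() != 3)
    stop("stride and pad must each have 3 elements");
  ConvGeom g;
  g.C = xd[0]; g.D = xd[1]; g.H = xd[2]; g.W = xd[3];
  g.Kd = wd[2]; g.Kh = wd[3]; g.Kw = wd[4];
  g.sd = stride[0]; g.sh = stride[1]; g.sw = stride[2];
  g.pd = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  if (wd[1] != g.C)
    stop("weight input channels (%d) do not match input (%d)", wd[1], g.C);
  g.Do = out_size(g.D, g.Kd, g.pd, g.sd);
  g.Ho = out_size(g.H, g.Kh, g.ph, g.sh);
  g.Wo = out_size(g.W, g.Kw, g.pw, g.sw);
  if (g.Do < 1 || g.Ho < 1 || g.Wo < 1) stop("output spatial size < 1");
  return g;
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, IntegerVector stride,
                                 IntegerVector pad) {
  IntegerVector xd = dims_of(x, 5, "x"), wd = dims_of(w, 5, "w");
  const ConvGeom g = make_geom(xd, wd, stride, pad);
  const int Cout = wd[0], N = xd[4], P = g.cols(), R = g.rows();
  if (b.size() != Cout) stop("bias length must equal output channels");

  NumericVector y((R_xlen_t)Cout * P * N);
  y.attr("dim") = IntegerVector::create(Cout, g.Do, g.Ho, g.Wo, N);
  arma::mat Wm(w.begin(), Cout, R, false, true);
  arma::mat Pm(R, P);
  arma::colvec bv(b.begin(), Cout, false, true);
  const R_xlen_t xstep = (R_xlen_t)g.C * g.D * g.H * g.W;
  const R_xlen_t ystep = (R_xlen_t)Cout * P;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, g, Pm);
    arma::mat Y(y.begin() + n * ystep, Cout, P, false, true);
    Y = Wm * Pm;
    Y.each_col() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = dims_of(x, 5, "x"), wd = dims_of(w, 5, "w");
  dims_of(dy, 5, "dy");
  const ConvGeom g = make_geom(xd, wd, stride, pad);
  const int Cout = wd[0], N = xd[4], P = g.cols(), R = g.rows();

  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), Cout, R, false, true);
  arma::mat dWm(dw.begin(), Cout, R, false, true);
  arma::colvec dbv(db.begin(), Cout, false, true);
  arma::mat Pm(R, P), dPm(R, P);
  const R_xlen_t xstep = (R_xlen_t)g.C * g.D * g.H * g.W;
  const R_xlen_t ystep = (R_xlen_t)Cout * P;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, g, Pm);
    arma::mat dY(const_cast<double*>(dy.begin()) + n * ystep, Cout, P,
                 false, true);
    dWm += dY * Pm.t();
    dbv += arma::sum(dY, 1);
    dPm = Wm.t() * dY;
    col2im_add(dPm, g, dx.begin() + n * xstep);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling with a per-axis kernel (1 or 2); stride equals the kernel.
// Returns the pooled array and 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool3d_forward_cpp(NumericVector x, IntegerVector k) {
  IntegerVector xd = dims_of(x, 5, "x");
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3], N = xd[4];
  if (k.size() != 3) stop("k must have 3 elements (depth, height, width)");
  const int kd = k[0], kh = k[1], kw = k[2];
  const int Do = D / kd, Ho = H / kh, Wo = W / kw;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("pooled size < 1");

  NumericVector y((R_xlen_t)C * Do * Ho * Wo * N);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  arg.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  const R_xlen_t DH = (R_xlen_t)D * H;
  const R_xlen_t xstep = (R_xlen_t)C * D * H * W;
  R_xlen_t yi = 0;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          for (int c = 0; c < C; ++c, ++yi) {
            double best = -std::numeric_limits<double>::infinity();
            R_xlen_t besti = -1;
            for (int dw_ = 0; dw_ < kw; ++dw_)
              for (int dh_ = 0; dh_ < kh; ++dh_)
                for (int dd = 0; dd < kd; ++dd) {
                  const R_xlen_t idx = c +
                    C * ((R_xlen_t)(od * kd + dd) + D * (oh * kh + dh_) +
                         DH * (ow * kw + dw_)) + n * xstep;
                  if (x[idx] > best) { best = x[idx]; besti = idx; }
                }
            y[yi] = best;
            arg[yi] = (int)(besti + 1);
          }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector argmax,
                                     IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}
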
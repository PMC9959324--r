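// Volumetric convolution / max-pooling kernels for the CNN training engine.
//
// Array layout convention (shared with the R side): dense 5-axis arrays in
// R's column-major order with dimensions (H, W, D, C, N) = (rows, columns,
// spectral depth, channels, batch).  Convolution weights are stored as
// (kh, kw, kd, Cin, Cout).  Convolutions use zero ("same") padding; pooling
// uses TensorFlow-style SAME padding with ceil(d/stride) output extents.
//
// The convolution is evaluated per sample as an im2col unfold followed by a
// BLAS matrix product, which is what makes CPU training of the four-block
// network practical.  A deliberately slow direct-summation oracle lives on
// the R side (conv3d_reference) and the two are cross-checked in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Fill the im2col matrix (K x HWD, K = kh*kw*kd*C) for one sample.
// xs points at the start of sample n inside the (H,W,D,C,N) array.
void im2col(const double* xs, int H, int W, int D, int C,
            int kh, int kw, int kd, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  const long HW = (long)H * W;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (long)c * HW * D;
    for (int r = 0; r < kd; ++r) {
      for (int q = 0; q < kw; ++q) {
        for (int p = 0; p < kh; ++p) {
          const int k = p + kh * (q + kw * (r + kd * c));
          for (int d = 0; d < D; ++d) {
            const int z = d + r - pd;
            if (z < 0 || z >= D) continue;
            for (int w = 0; w < W; ++w) {
              const int y = w + q - pw;
              if (y < 0 || y >= W) continue;
              const double* xcol = xc + (long)z * HW + (long)y * H;
              const long vox0 = (long)w * H + (long)d * HW;
              const int h0 = std::max(0, ph - p);
              const int h1 = std::min(H, H + ph - p);
              for (int h = h0; h < h1; ++h)
                col.at(k, vox0 + h) = xcol[h + p - ph];
            }
          }
        }
      }
    }
  }
}

// Scatter-add gcol (K x HWD) back into the gradient of one input sample.
void col2im(const arma::mat& gcol, int H, int W, int D, int C,
            int kh, int kw, int kd, double* gxs) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  const long HW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gxs + (long)c * HW * D;
    for (int r = 0; r < kd; ++r) {
      for (int q = 0; q < kw; ++q) {
        for (int p = 0; p < kh; ++p) {
          const int k = p + kh * (q + kw * (r + kd * c));
          for (int d = 0; d < D; ++d) {
            const int z = d + r - pd;
            if (z < 0 || z >= D) continue;
            for (int w = 0; w < W; ++w) {
              const int y = w + q - pw;
              if (y < 0 || y >= W) continue;
              double* gcol_dst = gc + (long)z * HW + (long)y * H;
              const long vox0 = (long)w * H + (long)d * HW;
              const int h0 = std::max(0, ph - p);
              const int h1 = std::min(H, H + ph - p);
              for (int h = h0; h < h1; ++h)
                gcol_dst[h + p - ph] += gcol.at(k, vox0 + h);
            }
          }
        }
      }
    }
  }
}

inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

} // namespace

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias, bool relu) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int kh = wd[0], kw = wd[1], kd = wd[2], Cin = wd[3], F = wd[4];
  if (Cin != C) stop("conv3d: input channel count does not match kernels");
  const long HWD = (long)H * W * D;
  const int K = kh * kw * kd * C;
  NumericVector out(Rcpp::no_init((R_xlen_t)HWD * F * N));
  arma::mat Wf(const_cast<double*>(w.begin()), K, F, false, true);
  arma::mat col(K, HWD);
  arma::rowvec b(const_cast<double*>(bias.begin()), F, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * HWD * C, H, W, D, C, kh, kw, kd, col);
    arma::mat G(out.begin() + (R_xlen_t)n * HWD * F, HWD, F, false, true);
    G = col.t() * Wf;
    G.each_row() += b;
    if (relu) G.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  out.attr("dim") = IntegerVector::create(H, W, D, F, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector out, NumericVector gout, bool relu) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int kh = wd[0], kw = wd[1], kd = wd[2], F = wd[4];
  const long HWD = (long)H * W * D;
  const int K = kh * kw * kd * C;
  NumericVector gx((R_xlen_t)HWD * C * N);
  NumericVector gw(w.size());
  NumericVector gb(F);
  arma::mat Wf(const_cast<double*>(w.begin()), K, F, false, true);
  arma::mat GW(gw.begin(), K, F, false, true);
  arma::rowvec GB(gb.begin(), F, false, true);
  arma::mat col(K, HWD);
  arma::mat gpre(HWD, F);
  for (int n = 0; n < N; ++n) {
    const double* on = out.begin() + (R_xlen_t)n * HWD * F;
    const double* gn = gout.begin() + (R_xlen_t)n * HWD * F;
    if (relu) {
      for (long i = 0; i < HWD * F; ++i)
        gpre.memptr()[i] = on[i] > 0.0 ? gn[i] : 0.0;
    } else {
      std::copy(gn, gn + HWD * F, gpre.memptr());
    }
    im2col(x.begin() + (R_xlen_t)n * HWD * C, H, W, D, C, kh, kw, kd, col);
    GW += col * gpre;
    GB += arma::sum(gpre, 0);
    arma::mat gcol = Wf * gpre.t();
    col2im(gcol, H, W, D, C, kh, kw, kd, gx.begin() + (R_xlen_t)n * HWD * C);
  }
  gx.attr("dim") = IntegerVector::create(H, W, D, C, N);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xd,
                       IntegerVector pool, IntegerVector stride) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int ph = pool[0], pw = pool[1], pd = pool[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int OH = ceil_div(H, sh), OW = ceil_div(W, sw), OD = ceil_div(D, sd);
  // TF SAME pooling: total pad = max((out-1)*stride + pool - in, 0),
  // split with the smaller half in front.
  const int bh = std::max((OH - 1) * sh + ph - H, 0) / 2;
  const int bw = std::max((OW - 1) * sw + pw - W, 0) / 2;
  const int bd = std::max((OD - 1) * sd + pd - D, 0) / 2;
  const long HW = (long)H * W, OHW = (long)OH * OW;
  const R_xlen_t nout = (R_xlen_t)OHW * OD * C * N;
  NumericVector out(Rcpp::no_init(nout));
  IntegerVector arg(Rcpp::no_init(nout));
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (R_xlen_t)(n * C + c) * HW * D;
      for (int od = 0; od < OD; ++od) {
        const int z0 = std::max(od * sd - bd, 0);
        const int z1 = std::min(od * sd - bd + pd, D);
        for (int ow = 0; ow < OW; ++ow) {
          const int y0 = std::max(ow * sw - bw, 0);
          const int y1 = std::min(ow * sw - bw + pw, W);
          for (int oh = 0; oh < OH; ++oh, ++o) {
            const int h0 = std::max(oh * sh - bh, 0);
            const int h1 = std::min(oh * sh - bh + ph, H);
            double best = R_NegInf;
            long besti = -1;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const double* p0 = xc + (long)z * HW + (long)y * H;
                for (int h = h0; h < h1; ++h)
                  if (p0[h] > best) {
                    best = p0[h];
                    besti = (long)z * HW + (long)y * H + h;
                  }
              }
            out[o] = best;
            arg[o] = (int)besti; // offset within this sample/channel slab
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, OD, C, N);
  return List::create(_["out"] = out, _["arg"] = arg,
                      _["odim"] = IntegerVector::create(OH, OW, OD, C, N));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector arg, NumericVector gout,
                                IntegerVector odim, IntegerVector xd) {
  const int OH = odim[0], OW = odim[1], OD = odim[2], C = odim[3], N = odim[4];
  const int H = xd[0], W = xd[1], D = xd[2];
  const long HWD = (long)H * W * D, OHWD = (long)OH * OW * OD;
  NumericVector gx((R_xlen_t)HWD * C * N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* g = gx.begin() + (R_xlen_t)(n * C + c) * HWD;
      for (long i = 0; i < OHWD; ++i, ++o) g[arg[o]] += gout[o];
    }
  gx.attr("dim") = xd;
  return gx;
}
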
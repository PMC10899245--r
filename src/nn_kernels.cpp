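// Convolution primitives for the segmentation network.
//
// Layout conventions (match R's column-major arrays):
//   activations: 4-D array (H, W, C, B)
//   conv weights: matrix (K*K*C_in, C_out), row index kh + K*(kw + K*c)
//   transposed-conv weights: matrix (K*K*C_out, C_in), same row ordering
// A stride-s, pad-p convolution maps H -> floor((H + 2p - K)/s) + 1; the
// transposed convolution is its exact adjoint, so its output size Ho must
// satisfy floor((Ho + 2p - K)/s) + 1 == Hi.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int n, int K, int stride, int pad) {
  return (n + 2 * pad - K) / stride + 1;
}

// Gather K*K*C patches of one (H,W,C) cube into (K*K*C) x (Ho*Wo).
static void im2col_one(const double* x, int H, int W, int C,
                       int K, int stride, int pad, arma::mat& cols) {
  const int Ho = conv_out(H, K, stride, pad);
  const int Wo = conv_out(W, K, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (size_t)H * W * c;
        for (int kw = 0; kw < K; ++kw) {
          const int cc = c0 + kw;
          for (int kh = 0; kh < K; ++kh) {
            const int rr = r0 + kh;
            dst[kh + K * (kw + K * c)] =
              (rr >= 0 && rr < H && cc >= 0 && cc < W)
                ? plane[rr + (size_t)H * cc] : 0.0;
          }
        }
      }
    }
  }
}

// Adjoint of im2col_one: scatter-add columns back into the (H,W,C) cube.
static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int K, int stride, int pad, double* x) {
  const int Ho = conv_out(H, K, stride, pad);
  const int Wo = conv_out(W, K, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* plane = x + (size_t)H * W * c;
        for (int kw = 0; kw < K; ++kw) {
          const int cc = c0 + kw;
          if (cc < 0 || cc >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int rr = r0 + kh;
            if (rr < 0 || rr >= H) continue;
            plane[rr + (size_t)H * cc] += src[kh + K * (kw + K * c)];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H, W, C, B) array");
  return d;
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                       int K, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = w.ncol();
  if (w.nrow() != K * K * C)
    stop("weight rows (%d) do not match K*K*C_in (%d)", w.nrow(), K * K * C);
  const int Ho = conv_out(H, K, stride, pad);
  const int Wo = conv_out(W, K, stride, pad);
  NumericVector out((size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::mat cols(K * K * C, Ho * Wo);
  arma::rowvec bias(b.begin(), Cout, false);
  for (int bi = 0; bi < B; ++bi) {
    im2col_one(x.begin() + (size_t)H * W * C * bi, H, W, C, K, stride, pad, cols);
    arma::mat o = cols.t() * wm;              // (Ho*Wo) x Cout
    o.each_row() += bias;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)Ho * Wo * Cout * bi);
  }
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix w, NumericVector gout,
              int K, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = w.ncol();
  const int Ho = conv_out(H, K, stride, pad);
  const int Wo = conv_out(W, K, stride, pad);
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  arma::mat dw(K * K * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat cols(K * K * C, Ho * Wo);
  for (int bi = 0; bi < B; ++bi) {
    im2col_one(x.begin() + (size_t)H * W * C * bi, H, W, C, K, stride, pad, cols);
    arma::mat g(const_cast<double*>(gout.begin()) + (size_t)Ho * Wo * Cout * bi,
                Ho * Wo, Cout, false);
    dw += cols * g;
    db += arma::sum(g, 0);
    arma::mat dcols = wm * g.t();             // (K*K*C) x (Ho*Wo)
    col2im_one(dcols, H, W, C, K, stride, pad,
               dx.begin() + (size_t)H * W * C * bi);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dw.begin(), dw.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution: output (Ho, Wo) given explicitly; implemented as the
// adjoint of the matching forward convolution.
// [[Rcpp::export(name = ".convt_fwd")]]
NumericVector convt_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                        int K, int stride, int pad, int Ho, int Wo) {
  IntegerVector d = dims4(x);
  const int Hi = d[0], Wi = d[1], Cin = d[2], B = d[3];
  const int Cout = w.nrow() / (K * K);
  if (w.nrow() != K * K * Cout || (int)w.ncol() != Cin)
    stop("transposed-conv weight shape mismatch");
  if (conv_out(Ho, K, stride, pad) != Hi || conv_out(Wo, K, stride, pad) != Wi)
    stop("requested output size is inconsistent with stride/pad/kernel");
  NumericVector out((size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat wm(w.begin(), w.nrow(), Cin, false);
  for (int bi = 0; bi < B; ++bi) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)Hi * Wi * Cin * bi,
                 Hi * Wi, Cin, false);
    arma::mat cols = wm * xm.t();             // (K*K*Cout) x (Hi*Wi)
    double* optr = out.begin() + (size_t)Ho * Wo * Cout * bi;
    col2im_one(cols, Ho, Wo, Cout, K, stride, pad, optr);
    for (int c = 0; c < Cout; ++c) {
      double* plane = optr + (size_t)Ho * Wo * c;
      for (int i = 0; i < Ho * Wo; ++i) plane[i] += b[c];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".convt_bwd")]]
List convt_bwd(NumericVector x, NumericMatrix w, NumericVector gout,
               int K, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int Hi = d[0], Wi = d[1], Cin = d[2], B = d[3];
  IntegerVector dg = dims4(gout);
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  arma::mat wm(w.begin(), w.nrow(), Cin, false);
  NumericVector dx((size_t)Hi * Wi * Cin * B);
  dx.attr("dim") = IntegerVector::create(Hi, Wi, Cin, B);
  arma::mat dw(K * K * Cout, Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat gcols(K * K * Cout, Hi * Wi);
  for (int bi = 0; bi < B; ++bi) {
    im2col_one(gout.begin() + (size_t)Ho * Wo * Cout * bi, Ho, Wo, Cout,
               K, stride, pad, gcols);
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)Hi * Wi * Cin * bi,
                 Hi * Wi, Cin, false);
    dw += gcols * xm;
    arma::mat dxm = gcols.t() * wm;           // (Hi*Wi) x Cin
    std::copy(dxm.begin(), dxm.end(), dx.begin() + (size_t)Hi * Wi * Cin * bi);
    const double* gptr = gout.begin() + (size_t)Ho * Wo * Cout * bi;
    for (int c = 0; c < Cout; ++c) {
      const double* plane = gptr + (size_t)Ho * Wo * c;
      for (int i = 0; i < Ho * Wo; ++i) db[c] += plane[i];
    }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dw.begin(), dw.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
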
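// Low-level numeric kernels for the encoder-decoder network and image ops.
// Arrays follow R's column-major layout: images are H x W x C, filters
// KH x KW x Cin x Cout. All convolutions use "same" zero padding, stride 1,
// and are evaluated as im2col + GEMM so the heavy lifting lands in BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Patch matrix: (H*W) x (KH*KW*Cin); column q = di + dj*KH + ci*KH*KW holds
// the channel-ci image shifted by (di-ph, dj-pw), zero outside the frame.
static arma::mat im2col(const double* xp, int H, int W, int Cin,
                        int KH, int KW) {
  const int ph = KH / 2, pw = KW / 2;
  const size_t HW = (size_t)H * W;
  arma::mat C((size_t)H * W, (size_t)KH * KW * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xp + (size_t)ci * HW;
    for (int dj = 0; dj < KW; ++dj) {
      for (int di = 0; di < KH; ++di) {
        double* col = C.colptr(di + dj * KH + (size_t)ci * KH * KW);
        const int off = di - ph;
        const int i0 = std::max(0, -off), i1 = std::min(H, H - off);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          const double* src = xc + (size_t)jj * H + off;
          double* dst = col + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
  return C;
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to the image.
static void col2im(const arma::mat& dC, double* dxp, int H, int W, int Cin,
                   int KH, int KW) {
  const int ph = KH / 2, pw = KW / 2;
  const size_t HW = (size_t)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* dxc = dxp + (size_t)ci * HW;
    for (int dj = 0; dj < KW; ++dj) {
      for (int di = 0; di < KH; ++di) {
        const double* col = dC.colptr(di + dj * KH + (size_t)ci * KH * KW);
        const int off = di - ph;
        const int i0 = std::max(0, -off), i1 = std::min(H, H - off);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          double* dst = dxc + (size_t)jj * H + off;
          const double* src = col + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  NumericVector y((size_t)H * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const arma::mat C = im2col(x.begin(), H, W, Cin, KH, KW);
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (size_t)KH * KW * Cin, Cout, false, true);
  arma::mat Y(y.begin(), (size_t)H * W, Cout, false, true);
  Y = C * Wm;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  const arma::mat C = im2col(x.begin(), H, W, Cin, KH, KW);
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (size_t)KH * KW * Cin, Cout, false, true);
  const arma::mat dY(const_cast<double*>(dy.begin()),
                     (size_t)H * W, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)KH * KW * Cin, Cout, false, true);
  dWm = C.t() * dY;
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dY.col(co));
  const arma::mat dC = dY * Wm.t();
  col2im(dC, dx.begin(), H, W, Cin, KH, KW);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);  // winner offset 0..3 = (di, dj) = (k%2, k/2)
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300;
        int bk = 0;
        for (int k = 0; k < 4; ++k) {
          const int di = k % 2, dj = k / 2;
          const double v = xc[(2 * i + di) + (size_t)(2 * j + dj) * H];
          if (v > best) { best = v; bk = k; }
        }
        const size_t o = i + (size_t)j * Ho + (size_t)c * Ho * Wo;
        yp[o] = best;
        ip[o] = bk;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2];
  NumericVector dx(H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const size_t o = i + (size_t)j * Ho + (size_t)c * Ho * Wo;
        const int k = ip[o];
        const int di = k % 2, dj = k / 2;
        dxp[(2 * i + di) + (size_t)(2 * j + dj) * H + (size_t)c * H * W] += dyp[o];
      }
    }
  }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  NumericVector y(4 * H * W * C);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = xp[i + (size_t)j * H + (size_t)c * H * W];
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            yp[(2 * i + di) + (size_t)(2 * j + dj) * 2 * H + (size_t)c * 4 * H * W] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx(H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            s += dyp[(2 * i + di) + (size_t)(2 * j + dj) * H2 + (size_t)c * H2 * W2];
        dxp[i + (size_t)j * H + (size_t)c * H * W] = s;
      }
    }
  }
  return dx;
}

// Connected-component labeling with 8-connectivity (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * H);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Bilinear sampling of img at fractional coordinates (mr, mc), 0-based.
// Out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericVector cpp_bilinear_warp(NumericVector img, NumericMatrix mr, NumericMatrix mc,
                                double fill) {
  IntegerVector xd = img.attr("dim");
  const int H = xd[0], W = xd[1];
  const int C = xd.size() > 2 ? xd[2] : 1;
  const int Ho = mr.nrow(), Wo = mr.ncol();
  NumericVector out(Ho * Wo * C);
  if (xd.size() > 2)
    out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  else
    out.attr("dim") = IntegerVector::create(Ho, Wo);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double r = mr(i, j), c = mc(i, j);
      const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      const double fr = r - r0, fc = c - c0;
      for (int ch = 0; ch < C; ++ch) {
        double acc = 0.0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int rr = r0 + di, cc = c0 + dj;
            const double wgt = (di ? fr : 1 - fr) * (dj ? fc : 1 - fc);
            double v;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) v = fill;
            else v = ip[rr + (size_t)cc * H + (size_t)ch * H * W];
            acc += wgt * v;
          }
        }
        op[i + (size_t)j * Ho + (size_t)ch * Ho * Wo] = acc;
      }
    }
  }
  return out;
}

// Separable convolution with an odd symmetric kernel, replicated edges.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_sep(NumericMatrix m, NumericVector k) {
  const int H = m.nrow(), W = m.ncol();
  const int p = (k.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -p; t <= p; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        acc += m(ii, j) * k[t + p];
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -p; t <= p; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        acc += tmp(i, jj) * k[t + p];
      }
      out(i, j) = acc;
    }
  }
  return out;
}
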
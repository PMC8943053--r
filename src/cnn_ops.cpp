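// Convolution and max-pool kernels for the worm/non-worm classifier.
// Arrays are R column-major with dims (H, W, C, B); convolution is 3x3,
// stride 1, zero ("same") padding, implemented as im2col + GEMM. The
// im2col row ordering is c * 9 + (dj + 1) * 3 + (di + 1), with di the row
// offset and dj the column offset; weight matrices must match it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, arma::mat& M) {
  // M: (9*C) x (H*W), preallocated
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int row = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double* src = xc + (size_t)js * H + i0 + di;
          double* dst = M.memptr() + (size_t)(j * H + i0) * M.n_rows + row;
          for (int i = i0; i < i1; ++i) {
            *dst = *src;
            ++src;
            dst += M.n_rows;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int row = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double* dst = xc + (size_t)js * H + i0 + di;
          const double* src = M.memptr() + (size_t)(j * H + i0) * M.n_rows + row;
          for (int i = i0; i < i1; ++i) {
            *dst += *src;
            ++dst;
            src += M.n_rows;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, IntegerVector dims,
                             const arma::mat& w, const arma::vec& b) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Cout = w.n_rows;
  if ((int)w.n_cols != 9 * C) stop("weight shape mismatch");
  NumericVector y((R_xlen_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat M(9 * C, H * W);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)bb * H * W * C, H, W, C, M);
    arma::mat Y = w * M; // Cout x HW
    Y.each_col() += b;
    arma::mat Yt = Y.t(); // HW x Cout, contiguous per channel
    std::copy(Yt.memptr(), Yt.memptr() + (size_t)H * W * Cout,
              y.begin() + (size_t)bb * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector dy, IntegerVector dims,
                     const arma::mat& w) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Cout = w.n_rows;
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  arma::mat dw(arma::size(w), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M(9 * C, H * W);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)bb * H * W * C, H, W, C, M);
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)bb * H * W * Cout,
                  H * W, Cout, false, true); // HW x Cout view
    arma::mat dY = dYt.t(); // Cout x HW
    dw += dY * M.t();
    db += arma::sum(dY, 1);
    arma::mat dM = w.t() * dY; // 9C x HW
    col2im_add(dM, H, W, C, dx.begin() + (size_t)bb * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward(NumericVector x, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xs = xp + (size_t)cb * H * W;
    size_t off = (size_t)cb * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int base = (2 * j) * H + 2 * i;
        int cand[4] = {base, base + 1, base + H, base + H + 1};
        int bi = cand[0];
        double bv = xs[cand[0]];
        for (int k = 1; k < 4; ++k) {
          if (xs[cand[k]] > bv) {
            bv = xs[cand[k]];
            bi = cand[k];
          }
        }
        *yp++ = bv;
        *ip++ = (int)(off + bi); // 0-based into the full input array
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector idx,
                               IntegerVector dims_in) {
  size_t n = (size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3];
  NumericVector dx(n);
  dx.attr("dim") = dims_in;
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) dxp[ip[k]] += dyp[k];
  return dx;
}
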
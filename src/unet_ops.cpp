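// Convolution and pooling primitives for the small segmentation U-net.
// Tensors are H x W x C cubes; 3x3 convolutions use same-padding and are
// implemented as shifted submatrix accumulations so the heavy lifting is
// dense matrix arithmetic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// y(i,j,co) = b[co] + sum_ci sum_{dy,dx in -1..1} w(dy,dx,ci,co) x(i+dy, j+dx, ci)
// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const Rcpp::NumericVector& w,
                      const arma::vec& b) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  cube y(H, W, cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co) {
    y.slice(co).fill(b[co]);
    for (int ci = 0; ci < cin; ++ci) {
      const mat& xs = x.slice(ci);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          double wv = wp[(dy + 1) + 3 * (dx + 1) + 9 * (ci + cin * co)];
          if (wv == 0.0) continue;
          int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
          int c0 = std::max(0, -dx), c1 = W - 1 - std::max(0, dx);
          if (r0 > r1 || c0 > c1) continue;
          y.slice(co).submat(r0, c0, r1, c1) +=
            wv * xs.submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx);
        }
      }
    }
  }
  return y;
}

// Gradients of the same convolution. Returns dx, dw, db.
// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const Rcpp::NumericVector& w,
                      const arma::cube& dy) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  cube dx(H, W, cin, fill::zeros);
  Rcpp::NumericVector dw(w.size());
  dw.attr("dim") = wd;
  vec db(cout);
  const double* wp = w.begin();
  double* dwp = dw.begin();
  for (int co = 0; co < cout; ++co) {
    const mat& g = dy.slice(co);
    db[co] = accu(g);
    for (int ci = 0; ci < cin; ++ci) {
      for (int ox = -1; ox <= 1; ++ox) {
        for (int oy = -1; oy <= 1; ++oy) {
          int r0 = std::max(0, -oy), r1 = H - 1 - std::max(0, oy);
          int c0 = std::max(0, -ox), c1 = W - 1 - std::max(0, ox);
          if (r0 > r1 || c0 > c1) continue;
          const size_t wi = (oy + 1) + 3 * (ox + 1) + 9 * (ci + cin * co);
          dwp[wi] += accu(g.submat(r0, c0, r1, c1) %
                          x.slice(ci).submat(r0 + oy, c0 + ox, r1 + oy, c1 + ox));
          dx.slice(ci).submat(r0 + oy, c0 + ox, r1 + oy, c1 + ox) +=
            wp[wi] * g.submat(r0, c0, r1, c1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled cube and the flat index of the
// winning input pixel per output pixel (for the backward pass).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector arg(Ho * Wo * C);
  int k = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xs(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        if (xs(2 * i + 1, 2 * j) > best) { best = xs(2 * i + 1, 2 * j); bi = 2 * i + 1; }
        if (xs(2 * i, 2 * j + 1) > best) { best = xs(2 * i, 2 * j + 1); bi = 2 * i; bj = 2 * j + 1; }
        if (xs(2 * i + 1, 2 * j + 1) > best) { best = xs(2 * i + 1, 2 * j + 1); bi = 2 * i + 1; bj = 2 * j + 1; }
        y(i, j, c) = best;
        arg[c * Ho * Wo + j * Ho + i] = c * H * W + bj * H + bi;  // column-major
        ++k;
      }
    }
  }
  (void)k;
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("arg") = arg);
}

// Scatter pooled gradients back to the winning input locations.
// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::cube& dy, const Rcpp::IntegerVector& arg,
                        int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double* g = dy.memptr();
  double* d = dx.memptr();
  for (int k = 0; k < (int)dy.n_elem; ++k) d[arg[k]] += g[k];
  return dx;
}
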
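// Low-level numeric kernels: 2-D convolution (same padding) with explicit
// backward passes, 2x2 max-pooling, nearest upsampling, image resizing, and
// the chi^2 / cyclic-DTW machinery of the temporal-consistency metric.
//
// Tensor layout everywhere: an R array dim c(H, W, C) maps onto an
// arma::cube with n_rows = H, n_cols = W, n_slices = C (both column-major).
// Convolution weights are a matrix of size (k*k*Cin) x Cout whose row index
// is i + k*(j + k*c) for kernel offset (i, j) and input channel c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, m = k / 2;
  mat out(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int col = i + k * (j + k * c);
        const int di = i - m, dj = j - m;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj;
          if (sw < 0 || sw >= W) continue;
          double* dst = out.colptr(col) + H * w;
          const double* src = x.slice_colptr(c, sw);
          const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + di];
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col_same
static cube col2im_same(const mat& g, const int H, const int W, const int C,
                        const int k) {
  const int m = k / 2;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int col = i + k * (j + k * c);
        const int di = i - m, dj = j - m;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj;
          if (sw < 0 || sw >= W) continue;
          const double* src = g.colptr(col) + H * w;
          double* dst = out.slice_colptr(c, sw);
          const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
          for (int h = h0; h < h1; ++h) dst[h + di] += src[h];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat col = im2col_same(x, k);
  mat o = col * w;
  o.each_row() += b.t();
  cube out(o.memptr(), H, W, Cout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gout, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  mat G(const_cast<double*>(gout.memptr()), H * W, Cout, false, true);
  mat col = im2col_same(x, k);
  mat gw = col.t() * G;
  vec gb = sum(G, 0).t();
  mat gcol = G * w.t();
  cube gx = col2im_same(gcol, H, W, C, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  icube idx(Ho, Wo, C);  // 0..3: which corner of the 2x2 block won
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double v00 = x(2 * h, 2 * w, c), v10 = x(2 * h + 1, 2 * w, c);
        const double v01 = x(2 * h, 2 * w + 1, c),
                     v11 = x(2 * h + 1, 2 * w + 1, c);
        double best = v00; int bi = 0;
        if (v10 > best) { best = v10; bi = 1; }
        if (v01 > best) { best = v01; bi = 2; }
        if (v11 > best) { best = v11; bi = 3; }
        out(h, w, c) = best;
        idx(h, w, c) = bi;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& g, const arma::icube& idx) {
  const int Ho = g.n_rows, Wo = g.n_cols, C = g.n_slices;
  cube out(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int bi = idx(h, w, c);
        out(2 * h + (bi & 1), 2 * w + (bi >> 1), c) = g(h, w, c);
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;
        out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v;
        out(2 * h + 1, 2 * w + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& g) {
  const int Ho = g.n_rows / 2, Wo = g.n_cols / 2, C = g.n_slices;
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        out(h, w, c) = g(2 * h, 2 * w, c) + g(2 * h + 1, 2 * w, c) +
                       g(2 * h, 2 * w + 1, c) + g(2 * h + 1, 2 * w + 1, c);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, const int oh,
                               const int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(oh, ow, C);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int w = 0; w < ow; ++w) {
    double fw = (w + 0.5) * sw - 0.5;
    fw = std::min(std::max(fw, 0.0), (double)(W - 1));
    const int w0 = (int)fw, w1 = std::min(w0 + 1, W - 1);
    const double aw = fw - w0;
    for (int h = 0; h < oh; ++h) {
      double fh = (h + 0.5) * sh - 0.5;
      fh = std::min(std::max(fh, 0.0), (double)(H - 1));
      const int h0 = (int)fh, h1 = std::min(h0 + 1, H - 1);
      const double ah = fh - h0;
      for (int c = 0; c < C; ++c)
        out(h, w, c) = (1 - ah) * (1 - aw) * x(h0, w0, c) +
                       ah * (1 - aw) * x(h1, w0, c) +
                       (1 - ah) * aw * x(h0, w1, c) +
                       ah * aw * x(h1, w1, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::imat cpp_resize_nearest(const arma::imat& x, const int oh,
                              const int ow) {
  const int H = x.n_rows, W = x.n_cols;
  imat out(oh, ow);
  for (int w = 0; w < ow; ++w) {
    int sw = (int)((w + 0.5) * W / ow);
    sw = std::min(sw, W - 1);
    for (int h = 0; h < oh; ++h) {
      int sh = (int)((h + 0.5) * H / oh);
      sh = std::min(sh, H - 1);
      out(h, w) = x(sh, sw);
    }
  }
  return out;
}

// chi^2 distance matrix between two sets of (row-normalized) histograms
// [[Rcpp::export]]
arma::mat cpp_chi2_cost(const arma::mat& A, const arma::mat& B) {
  const int n1 = A.n_rows, n2 = B.n_rows, K = A.n_cols;
  mat out(n1, n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double a = A(i, k), b = B(j, k), d = a - b, q = a + b;
        if (q > 1e-12) s += d * d / q;
      }
      out(i, j) = 0.5 * s;
    }
  return out;
}

// Plain order-preserving DTW total cost for one fixed start alignment
// (exported separately so the dynamic program can be checked against
// exhaustive alignment enumeration).
// [[Rcpp::export]]
double cpp_dtw_total(const arma::mat& cost) {
  const int n1 = cost.n_rows, n2 = cost.n_cols;
  mat D(n1, n2);
  D(0, 0) = cost(0, 0);
  for (int j = 1; j < n2; ++j) D(0, j) = D(0, j - 1) + cost(0, j);
  for (int i = 1; i < n1; ++i) {
    D(i, 0) = D(i - 1, 0) + cost(i, 0);
    for (int j = 1; j < n2; ++j)
      D(i, j) = std::min({D(i - 1, j - 1), D(i - 1, j), D(i, j - 1)}) +
                cost(i, j);
  }
  return D(n1 - 1, n2 - 1);
}

// Order-preserving DTW over all cyclic rotations of the second sequence.
// cost: n1 x n2 matrix of pairwise point costs.  Returns the minimum over
// rotations of (total cost of optimal monotone alignment) / (path length),
// i.e. the mean cost per matched point, plus the winning rotation offset.
// [[Rcpp::export]]
Rcpp::List cpp_cyclic_dtw(const arma::mat& cost) {
  const int n1 = cost.n_rows, n2 = cost.n_cols;
  double best = datum::inf;
  int best_off = 0, best_len = 0;
  mat D(n1, n2);
  imat ch(n1, n2);  // 0 diag, 1 up (i-1), 2 left (j-1)
  for (int off = 0; off < n2; ++off) {
    // rotated column index: jr = (j + off) % n2
    D(0, 0) = cost(0, off % n2);
    ch(0, 0) = -1;
    for (int j = 1; j < n2; ++j) {
      D(0, j) = D(0, j - 1) + cost(0, (j + off) % n2);
      ch(0, j) = 2;
    }
    for (int i = 1; i < n1; ++i) {
      D(i, 0) = D(i - 1, 0) + cost(i, off % n2);
      ch(i, 0) = 1;
      for (int j = 1; j < n2; ++j) {
        const double cd = D(i - 1, j - 1), cu = D(i - 1, j),
                     cl = D(i, j - 1);
        double m = cd; int c = 0;
        if (cu < m) { m = cu; c = 1; }
        if (cl < m) { m = cl; c = 2; }
        D(i, j) = m + cost(i, (j + off) % n2);
        ch(i, j) = c;
      }
    }
    // path length by backtracking
    int i = n1 - 1, j = n2 - 1, len = 1;
    while (i > 0 || j > 0) {
      const int c = ch(i, j);
      if (c == 0) { --i; --j; }
      else if (c == 1) --i;
      else --j;
      ++len;
    }
    const double mean_cost = D(n1 - 1, n2 - 1) / len;
    if (mean_cost < best) {
      best = mean_cost;
      best_off = off;
      best_len = len;
    }
  }
  return List::create(_["mean_cost"] = best, _["offset"] = best_off,
                      _["path_len"] = best_len);
}
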
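// Compiled kernels for the NCA perception convolutions: im2col-style
// forward and backward passes over the stacked cell-state matrix
// (N x C, N = batch * h * w, pixels column-major per image, images stacked).
// Weight layout matches the R side: row (c * k * k + j) of W holds the
// weight for input channel c at offset j, offsets ordered dr-fastest over
// the k x k neighbourhood. Out-of-image neighbours are zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_stack(const arma::mat& S, int h, int w, int b,
                              int k) {
  const int r = k / 2, kk = k * k, C = S.n_cols, hw = h * w;
  const int N = b * hw;
  arma::mat X(N, kk * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = S.colptr(c);
    for (int j = 0; j < kk; ++j) {
      const int dr = j % k - r, dc = j / k - r;
      double* dst = X.colptr(c * kk + j);
      for (int bi = 0; bi < b; ++bi) {
        const int base = bi * hw;
        const int c0 = std::max(0, -dc), c1 = std::min(w, w - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
        for (int cc = c0; cc < c1; ++cc) {
          const double* s = src + base + (cc + dc) * h + (r0 + dr);
          double* d = dst + base + cc * h + r0;
          std::copy(s, s + (r1 - r0), d);
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& S, const arma::mat& W,
                       const arma::vec& bias, int h, int w, int b, int k) {
  arma::mat out = im2col_stack(S, h, w, b, k) * W;
  out.each_row() += bias.t();
  return out;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& dOut, const arma::mat& S,
                  const arma::mat& W, int h, int w, int b, int k) {
  const int r = k / 2, kk = k * k, C = S.n_cols, hw = h * w;
  const int N = b * hw;
  arma::mat X = im2col_stack(S, h, w, b, k);
  arma::mat dW = X.t() * dOut;
  arma::rowvec db = arma::sum(dOut, 0);
  arma::mat dX = dOut * W.t();            // N x kk*C
  arma::mat dS(N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dS.colptr(c);
    for (int j = 0; j < kk; ++j) {
      const int dr = j % k - r, dc = j / k - r;
      const double* src = dX.colptr(c * kk + j);
      for (int bi = 0; bi < b; ++bi) {
        const int base = bi * hw;
        const int c0 = std::max(0, -dc), c1 = std::min(w, w - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
        for (int cc = c0; cc < c1; ++cc) {
          const double* s = src + base + cc * h + r0;
          double* d = dst + base + (cc + dc) * h + (r0 + dr);
          for (int rr = 0; rr < r1 - r0; ++rr) d[rr] += s[rr];
        }
      }
    }
  }
  return List::create(Named("dS") = dS, Named("dW") = dW,
                      Named("db") = db.t());
}

// SLIC assignment/update iterations: k-means in (intensity, row, col) with
// a 2S x 2S spatial search window per cluster. `centers` is (K x 3):
// row, col (1-based) and intensity. Returns the final 1-based label vector
// (pixels column-major) after `iters` rounds.
// [[Rcpp::export(name = ".slic_iterate_cpp")]]
IntegerVector slic_iterate_cpp(const arma::vec& vals, int h, int w,
                               arma::mat centers, double S, double m,
                               int iters) {
  const int n = h * w, K = centers.n_rows;
  IntegerVector lab(n);
  std::vector<double> best(n);
  const double ratio = (m / S) * (m / S);
  for (int it = 0; it < iters; ++it) {
    std::fill(best.begin(), best.end(), std::numeric_limits<double>::max());
    std::fill(lab.begin(), lab.end(), 1);
    for (int k = 0; k < K; ++k) {
      const double cr = centers(k, 0), cc = centers(k, 1), ci = centers(k, 2);
      const int r0 = std::max(0, (int)std::floor(cr - 2 * S) - 1);
      const int r1 = std::min(h - 1, (int)std::ceil(cr + 2 * S) - 1);
      const int c0 = std::max(0, (int)std::floor(cc - 2 * S) - 1);
      const int c1 = std::min(w - 1, (int)std::ceil(cc + 2 * S) - 1);
      for (int cc2 = c0; cc2 <= c1; ++cc2) {
        const double dc = (cc2 + 1) - cc;
        for (int rr = r0; rr <= r1; ++rr) {
          const int p = rr + cc2 * h;
          const double dv = vals[p] - ci;
          const double dr = (rr + 1) - cr;
          const double d2 = dv * dv + ratio * (dr * dr + dc * dc);
          if (d2 < best[p]) { best[p] = d2; lab[p] = k + 1; }
        }
      }
    }
    arma::vec sr(K, arma::fill::zeros), sc(K, arma::fill::zeros),
      sv(K, arma::fill::zeros), cnt(K, arma::fill::zeros);
    for (int p = 0; p < n; ++p) {
      const int k = lab[p] - 1;
      sr[k] += p % h + 1;
      sc[k] += p / h + 1;
      sv[k] += vals[p];
      cnt[k] += 1;
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0) {
        centers(k, 0) = sr[k] / cnt[k];
        centers(k, 1) = sc[k] / cnt[k];
        centers(k, 2) = sv[k] / cnt[k];
      }
    }
  }
  return lab;
}

// Batch normalisation over columns with externally supplied statistics:
// out = (D - mu) * inv * gamma + beta, computed in one pass.
// [[Rcpp::export(name = ".bn_scale_cpp")]]
arma::mat bn_scale_cpp(const arma::mat& D, const arma::vec& mu,
                       const arma::vec& inv, const arma::vec& gamma,
                       const arma::vec& beta) {
  arma::mat out(D.n_rows, D.n_cols);
  for (arma::uword c = 0; c < D.n_cols; ++c) {
    const double sc = inv[c] * gamma[c];
    const double sh = beta[c] - mu[c] * sc;
    const double* s = D.colptr(c);
    double* d = out.colptr(c);
    for (arma::uword i = 0; i < D.n_rows; ++i) d[i] = s[i] * sc + sh;
  }
  return out;
}

// Batch-norm backward pass (population statistics). In training mode the
// dependence of mu/var on the batch is included; in eval mode the
// statistics are constants.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(const arma::mat& dY, const arma::mat& D,
                const arma::vec& mu, const arma::vec& inv,
                const arma::vec& gamma, bool training) {
  const arma::uword n = dY.n_rows, C = dY.n_cols;
  arma::mat dD(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* y = dY.colptr(c);
    const double* d = D.colptr(c);
    double* o = dD.colptr(c);
    const double ic = inv[c], mc = mu[c], gc = gamma[c];
    double sg = 0, sb = 0;
    for (arma::uword i = 0; i < n; ++i) {
      const double dh = (d[i] - mc) * ic;
      sg += y[i] * dh;
      sb += y[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    if (training) {
      const double m1 = sb / n, m2 = sg / n;
      for (arma::uword i = 0; i < n; ++i) {
        const double dh = (d[i] - mc) * ic;
        o[i] = (y[i] * gc - m1 * gc - dh * m2 * gc) * ic;
      }
    } else {
      const double sc = gc * ic;
      for (arma::uword i = 0; i < n; ++i) o[i] = y[i] * sc;
    }
  }
  return List::create(Named("dD") = dD, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
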
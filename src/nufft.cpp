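// [[Rcpp::depends(RcppArmadillo)]]
#include "gridding.h"
using namespace arma;

// Type-2 NUFFT: evaluate the Fourier sum of an N x N image at arbitrary
// k-space coordinates (cycles/pixel in [-0.5, 0.5)).
// [[Rcpp::export]]
arma::cx_vec cpp_nufft_forward(const arma::cx_mat& img, const arma::vec& kx,
                               const arma::vec& ky, int os, int W) {
  GridPlan P(img.n_rows, os, W);
  cx_mat Fp = img_to_grid(img, P);
  int M = kx.n_elem;
  cx_vec out(M);
  TapSet T;
  for (int m = 0; m < M; m++) {
    make_taps(P.ucoord(kx[m]), P.ucoord(ky[m]), P, T);
    out[m] = grid_interp(Fp, T);
  }
  return out;
}

// Type-1 (adjoint) NUFFT: weight samples, spread onto the oversampled grid,
// inverse FFT, crop and deapodize. Exact adjoint of cpp_nufft_forward when
// w == 1.
// [[Rcpp::export]]
arma::cx_mat cpp_nufft_adjoint(const arma::cx_vec& samples, const arma::vec& kx,
                               const arma::vec& ky, const arma::vec& w, int N,
                               int os, int W) {
  GridPlan P(N, os, W);
  cx_mat H(P.G, P.G, fill::zeros);
  int M = kx.n_elem;
  TapSet T;
  for (int m = 0; m < M; m++) {
    make_taps(P.ucoord(kx[m]), P.ucoord(ky[m]), P, T);
    grid_spread(H, samples[m] * w[m], T);
  }
  return grid_to_img(H, P);
}

// [[Rcpp::export]]
arma::cx_mat cpp_apply_rigid(const arma::cx_mat& img, double tx, double ty,
                             double theta) {
  return rigid_transform(img, tx, ty, theta);
}
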
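// [[Rcpp::depends(RcppArmadillo)]]
#include "gridding.h"
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// Shared helpers -----------------------------------------------------------

static void precompute_taps(const vec& kx, const vec& ky, const GridPlan& P,
                            std::vector<TapSet>& taps) {
  int M = kx.n_elem;
  taps.resize(M);
  for (int m = 0; m < M; m++)
    make_taps(P.ucoord(kx[m]), P.ucoord(ky[m]), P, taps[m]);
}

// Iterative SENSE ----------------------------------------------------------
//
// Solves the weighted normal equations
//   (C^H S^H W S C) x = C^H S^H W k,   W = diag(dcf)
// by conjugate gradient with zero initialization. kdata is M x Nc, coils is
// N x N x Nc, coords are cycles/pixel.
// [[Rcpp::export]]
List cpp_cg_sense(const arma::cx_mat& kdata, const arma::vec& kx,
                  const arma::vec& ky, const arma::vec& dcf,
                  const arma::cx_cube& coils, int max_iter, double tol,
                  int os, int W) {
  const int N = coils.n_rows, Nc = coils.n_slices, M = kx.n_elem;
  GridPlan P(N, os, W);
  std::vector<TapSet> taps;
  precompute_taps(kx, ky, P, taps);

  // normal operator
  auto AHWA = [&](const cx_mat& x) {
    cx_mat z(N, N, fill::zeros);
    for (int c = 0; c < Nc; c++) {
      cx_mat Fp = img_to_grid(x % coils.slice(c), P);
      cx_mat H(P.G, P.G, fill::zeros);
      for (int m = 0; m < M; m++)
        grid_spread(H, grid_interp(Fp, taps[m]) * dcf[m], taps[m]);
      z += conj(coils.slice(c)) % grid_to_img(H, P);
    }
    return z;
  };

  // right-hand side C^H S^H W k
  cx_mat b(N, N, fill::zeros);
  for (int c = 0; c < Nc; c++) {
    cx_mat H(P.G, P.G, fill::zeros);
    for (int m = 0; m < M; m++)
      grid_spread(H, kdata(m, c) * dcf[m], taps[m]);
    b += conj(coils.slice(c)) % grid_to_img(H, P);
  }

  cx_mat x(N, N, fill::zeros), r = b, p = b;
  double rs = std::real(cdot(vectorise(r), vectorise(r)));
  double rs0 = rs;
  std::vector<double> resnorm;
  resnorm.push_back(std::sqrt(rs));
  for (int it = 0; it < max_iter; it++) {
    if (rs <= tol * tol * rs0) break;
    cx_mat q = AHWA(p);
    double pq = std::real(cdot(vectorise(p), vectorise(q)));
    if (pq <= 0) break;
    double alpha = rs / pq;
    x += alpha * p;
    r -= alpha * q;
    double rs_new = std::real(cdot(vectorise(r), vectorise(r)));
    resnorm.push_back(std::sqrt(rs_new));
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  return List::create(Named("image") = x, Named("resnorm") = resnorm);
}

// Low-rank (subspace) inversion --------------------------------------------
//
// Solves min_I || S U_R F C I - K ||^2_W over R coefficient images. The
// per-time-point forward combines the R coefficient images with row n of
// U_R, coil-weights, and samples spoke n. Implemented in the oversampled
// k-space domain: one FFT grid per (coefficient, coil), interpolated per
// spoke with the temporal weight applied at the sample level.
//
// kdata: Ns x Nc x Nt; kx, ky, dcf: Ns x Nt; U: Nt x R.
// [[Rcpp::export]]
List cpp_low_rank_inversion(const arma::cx_cube& kdata, const arma::mat& kx,
                            const arma::mat& ky, const arma::mat& dcf,
                            const arma::cx_cube& coils, const arma::cx_mat& U,
                            int max_iter, double tol, int os, int W) {
  const int N = coils.n_rows, Nc = coils.n_slices;
  const int Ns = kx.n_rows, Nt = kx.n_cols, R = U.n_cols;
  GridPlan P(N, os, W);

  // tap tables per sample (Ns*Nt); memory ~ (W+1)*2*(8+4) bytes per sample
  std::vector<TapSet> taps((size_t)Ns * Nt);
  for (int n = 0; n < Nt; n++)
    for (int s = 0; s < Ns; s++)
      make_taps(P.ucoord(kx(s, n)), P.ucoord(ky(s, n)), P, taps[(size_t)n * Ns + s]);

  std::vector<cx_mat> Gr((size_t)R * Nc), Hr((size_t)R * Nc);

  // z = A^H W A x  (x: N x N x R)
  auto normal_op = [&](const cx_cube& x) {
    for (int r = 0; r < R; r++)
      for (int c = 0; c < Nc; c++)
        Gr[(size_t)r * Nc + c] = img_to_grid(x.slice(r) % coils.slice(c), P);
    for (int r = 0; r < R; r++)
      for (int c = 0; c < Nc; c++)
        Hr[(size_t)r * Nc + c].zeros(P.G, P.G);
    std::vector<cx_double> val((size_t)R * Nc);
    for (int n = 0; n < Nt; n++) {
      for (int s = 0; s < Ns; s++) {
        const TapSet& T = taps[(size_t)n * Ns + s];
        for (int r = 0; r < R; r++)
          for (int c = 0; c < Nc; c++)
            val[(size_t)r * Nc + c] = grid_interp(Gr[(size_t)r * Nc + c], T);
        for (int c = 0; c < Nc; c++) {
          cx_double y(0.0, 0.0);
          for (int r = 0; r < R; r++) y += U(n, r) * val[(size_t)r * Nc + c];
          y *= dcf(s, n);
          for (int r = 0; r < R; r++)
            grid_spread(Hr[(size_t)r * Nc + c], std::conj(U(n, r)) * y, T);
        }
      }
    }
    cx_cube z(N, N, R, fill::zeros);
    for (int r = 0; r < R; r++)
      for (int c = 0; c < Nc; c++)
        z.slice(r) += conj(coils.slice(c)) % grid_to_img(Hr[(size_t)r * Nc + c], P);
    return z;
  };

  // b = A^H W k
  cx_cube b(N, N, R, fill::zeros);
  for (int r = 0; r < R; r++)
    for (int c = 0; c < Nc; c++)
      Hr[(size_t)r * Nc + c].zeros(P.G, P.G);
  for (int n = 0; n < Nt; n++) {
    for (int s = 0; s < Ns; s++) {
      const TapSet& T = taps[(size_t)n * Ns + s];
      for (int c = 0; c < Nc; c++) {
        cx_double y = kdata(s, c, n) * dcf(s, n);
        for (int r = 0; r < R; r++)
          grid_spread(Hr[(size_t)r * Nc + c], std::conj(U(n, r)) * y, T);
      }
    }
  }
  for (int r = 0; r < R; r++)
    for (int c = 0; c < Nc; c++)
      b.slice(r) += conj(coils.slice(c)) % grid_to_img(Hr[(size_t)r * Nc + c], P);

  cx_cube x(N, N, R, fill::zeros), rr = b, p = b;
  double rs = std::real(cdot(vectorise(rr), vectorise(rr)));
  double rs0 = rs;
  std::vector<double> resnorm;
  resnorm.push_back(std::sqrt(rs));
  for (int it = 0; it < max_iter; it++) {
    if (rs <= tol * tol * rs0) break;
    cx_cube q = normal_op(p);
    double pq = std::real(cdot(vectorise(p), vectorise(q)));
    if (pq <= 0) break;
    double alpha = rs / pq;
    x += alpha * p;
    rr -= alpha * q;
    double rs_new = std::real(cdot(vectorise(rr), vectorise(rr)));
    resnorm.push_back(std::sqrt(rs_new));
    p = rr + (rs_new / rs) * p;
    rs = rs_new;
  }
  return List::create(Named("coeffs") = x, Named("resnorm") = resnorm);
}
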
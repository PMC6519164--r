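// [[Rcpp::depends(RcppArmadillo)]]
#include "gridding.h"
using namespace arma;

// Multi-coil radial MRF k-space simulation.
//
// comp:  N x N x Ntis complex component maps (M0 restricted to each unique
//        (T1,T2) tissue class);
// fp:    Nt x Ntis fingerprints of those classes;
// tx,ty: per-time-point translation in pixels; theta in radians (object pose
//        applied in image domain before coil weighting);
// kx,ky: Ns x Nt spoke coordinates (cycles/pixel);
// coils: N x N x Nc sensitivities.
// Returns Ns x Nc x Nt noiseless samples; noise is added by the R caller.
//
// Per time point the contrast image sum_t fp(n,t)*comp_t is moved to pose n,
// coil weighted and sampled on spoke n with the gridding NUFFT. Consecutive
// identical poses reuse the transformed component maps, which makes
// piecewise-constant (abrupt) motion cheap.
// [[Rcpp::export]]
arma::cx_cube cpp_simulate_kspace(const arma::cx_cube& comp,
                                  const arma::cx_mat& fp, const arma::vec& tx,
                                  const arma::vec& ty, const arma::vec& theta,
                                  const arma::mat& kx, const arma::mat& ky,
                                  const arma::cx_cube& coils, int os, int W) {
  const int N = comp.n_rows, Ntis = comp.n_slices, Nc = coils.n_slices;
  const int Ns = kx.n_rows, Nt = kx.n_cols;
  GridPlan P(N, os, W);

  cx_cube out(Ns, Nc, Nt, fill::zeros);
  cx_cube moved(N, N, Ntis);
  double ptx = datum::nan, pty = datum::nan, pth = datum::nan;
  TapSet T;

  for (int n = 0; n < Nt; n++) {
    if (!(tx[n] == ptx && ty[n] == pty && theta[n] == pth)) {
      for (int t = 0; t < Ntis; t++) {
        if (tx[n] == 0.0 && ty[n] == 0.0 && theta[n] == 0.0)
          moved.slice(t) = comp.slice(t);
        else
          moved.slice(t) = rigid_transform(comp.slice(t), tx[n], ty[n], theta[n]);
      }
      ptx = tx[n]; pty = ty[n]; pth = theta[n];
    }
    cx_mat contrast(N, N, fill::zeros);
    for (int t = 0; t < Ntis; t++) contrast += fp(n, t) * moved.slice(t);
    for (int c = 0; c < Nc; c++) {
      cx_mat Fp = img_to_grid(contrast % coils.slice(c), P);
      for (int s = 0; s < Ns; s++) {
        make_taps(P.ucoord(kx(s, n)), P.ucoord(ky(s, n)), P, T);
        out(s, c, n) = grid_interp(Fp, T);
      }
    }
    if (n % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// k-space-domain variant: the motion-free coil-weighted k-space of each
// tissue class is synthesized once, and motion enters exactly as rotated
// sampling coordinates plus translation phase ramps (the rigid-motion
// relation between moved and static spectra). No interpolation of the
// object is involved, so correcting with the same trajectory inverts the
// motion to machine precision. Arguments as in cpp_simulate_kspace.
// [[Rcpp::export]]
arma::cx_cube cpp_simulate_kspace_rotated(const arma::cx_cube& comp,
                                          const arma::cx_mat& fp,
                                          const arma::vec& tx, const arma::vec& ty,
                                          const arma::vec& theta,
                                          const arma::mat& kx, const arma::mat& ky,
                                          const arma::cx_cube& coils,
                                          int os, int W) {
  const int N = comp.n_rows, Ntis = comp.n_slices, Nc = coils.n_slices;
  const int Ns = kx.n_rows, Nt = kx.n_cols;
  GridPlan P(N, os, W);

  // static grids per (tissue, coil)
  std::vector<cx_mat> Gtc((size_t)Ntis * Nc);
  for (int t = 0; t < Ntis; t++)
    for (int c = 0; c < Nc; c++)
      Gtc[(size_t)t * Nc + c] = img_to_grid(comp.slice(t) % coils.slice(c), P);

  cx_cube out(Ns, Nc, Nt, fill::zeros);
  TapSet T;
  for (int n = 0; n < Nt; n++) {
    double ct = std::cos(-theta[n]), st = std::sin(-theta[n]);
    for (int s = 0; s < Ns; s++) {
      double k1 = kx(s, n), k2 = ky(s, n);
      double r1 = ct * k1 - st * k2;   // R_{-theta} k
      double r2 = st * k1 + ct * k2;
      make_taps(P.ucoord(r1), P.ucoord(r2), P, T);
      double ph = -2.0 * M_PI * (k1 * tx[n] + k2 * ty[n]);
      cx_double phase(std::cos(ph), std::sin(ph));
      for (int c = 0; c < Nc; c++) {
        cx_double acc(0.0, 0.0);
        for (int t = 0; t < Ntis; t++)
          acc += fp(n, t) * grid_interp(Gtc[(size_t)t * Nc + c], T);
        out(s, c, n) = acc * phase;
      }
    }
    if (n % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
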
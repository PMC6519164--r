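// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Extended phase graph simulation of an inversion-prepared, gradient-spoiled
// (FISP-type), variable flip angle, fixed-TR fingerprinting sequence.
//
// States are stored as Fp[k] = F_k, Fm[k] = conj(F_{-k}), Z[k] for
// k = 0..kmax. Per TR: RF rotation (constant phase, about x), signal
// recording (F0 attenuated by exp(-TE/T2)), T1/T2 relaxation with Z0
// recovery over the full TR, then a unit gradient-spoiler shift of the F
// configuration states.
//
// t1, t2: per-atom relaxation times (ms); fa_deg: flip angle train (deg);
// scales: slice-profile flip-angle scales (result is their mean); the
// inversion, when enabled, is an ideal 180 not affected by the scale.
// Returns Nt x Natoms complex fingerprints.
// [[Rcpp::export]]
arma::cx_mat cpp_epg_fisp(const arma::vec& t1, const arma::vec& t2,
                          const arma::vec& fa_deg, double tr, double te,
                          const arma::vec& scales, bool invert, int kmax) {
  const int Nt = fa_deg.n_elem, Na = t1.n_elem, Np = scales.n_elem;
  const int K = std::max(1, kmax);
  cx_mat out(Nt, Na, fill::zeros);
  const cx_double I(0.0, 1.0);

  cx_vec Fp(K + 1), Fm(K + 1), Z(K + 1);

  for (int a = 0; a < Na; a++) {
    double E1 = std::exp(-tr / t1[a]);
    double E2 = std::exp(-tr / t2[a]);
    double Ete = std::exp(-te / t2[a]);
    for (int p = 0; p < Np; p++) {
      Fp.zeros(); Fm.zeros(); Z.zeros();
      Z[0] = invert ? -1.0 : 1.0;
      int khi = 0;  // highest populated order, grows by one per TR
      for (int n = 0; n < Nt; n++) {
        double al = scales[p] * fa_deg[n] * M_PI / 180.0;
        double ca = std::cos(al), sa = std::sin(al);
        double c2 = std::cos(al / 2.0), s2 = std::sin(al / 2.0);
        double T11 = c2 * c2, T12 = s2 * s2;
        // RF rotation about x (phase 0): mixes (F_k, conj(F_-k), Z_k)
        for (int k = 0; k <= khi; k++) {
          cx_double fp = Fp[k], fm = Fm[k], z = Z[k];
          Fp[k] = T11 * fp + T12 * fm - I * sa * z;
          Fm[k] = T12 * fp + T11 * fm + I * sa * z;
          Z[k]  = -I * 0.5 * sa * fp + I * 0.5 * sa * fm + ca * z;
        }
        out(n, a) += Fp[0] * Ete;
        // relaxation + recovery over TR
        for (int k = 0; k <= khi; k++) {
          Fp[k] *= E2; Fm[k] *= E2; Z[k] *= E1;
        }
        Z[0] += 1.0 - E1;
        // unit gradient spoiler: F_k -> F_{k+1}
        if (khi < K) khi++;
        for (int k = khi; k >= 1; k--) Fp[k] = Fp[k - 1];
        Fp[0] = std::conj(Fm[1]);
        for (int k = 0; k < khi; k++) Fm[k] = Fm[k + 1];
        Fm[khi] = 0.0;
      }
    }
    if (a % 32 == 0) Rcpp::checkUserInterrupt();
  }
  out /= (double)Np;
  return out;
}
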
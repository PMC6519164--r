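#pragma once
#include <RcppArmadillo.h>
#include <Rmath.h>

// Kaiser-Bessel gridding machinery shared by the NUFFT, the CG-SENSE solver,
// the low-rank inversion and the k-space simulator.
//
// Conventions:
//  * image pixels are indexed 0..N-1 per dimension; the object/rotation
//    centre and the k-space DC both live at index N/2;
//  * k-space coordinates are in cycles/pixel, normalized to [-0.5, 0.5);
//  * the oversampled grid has G = os*N points, so a coordinate k maps to
//    the (periodic) grid position u = k*G mod G.

struct GridPlan {
  int N, G, W;
  double beta;
  arma::vec deapod;   // length N, separable apodization correction
  arma::vec lut;      // kernel values over [0, W/2]
  double lut_step;
  int lut_n;

  GridPlan(int N_, int os, int W_) : N(N_), G(os * N_), W(W_) {
    // Beatty et al. optimal beta for oversampling ratio os
    double s = (double)os;
    beta = M_PI * std::sqrt((double)W * W / (s * s) * (s - 0.5) * (s - 0.5) - 0.8);
    lut_n = 8193;
    lut_step = (W / 2.0) / (lut_n - 1);
    lut.set_size(lut_n);
    for (int i = 0; i < lut_n; i++) {
      double u = i * lut_step;
      double t = 1.0 - std::pow(2.0 * u / W, 2);
      lut[i] = (t <= 0.0) ? ((t == 0.0) ? 1.0 : 0.0)
                          : R::bessel_i(beta * std::sqrt(t), 0.0, 1.0);
    }
    lut[lut_n - 1] = 0.0;
    // Deapodization: continuous Fourier transform of the kernel sampled at
    // image-pixel frequencies xc/G, computed by Simpson integration (robust
    // against sign/branch slips of the closed form).
    deapod.set_size(N);
    const int nq = 2001;
    double h = (double)W / (nq - 1);
    arma::vec ku(nq), kv(nq);
    for (int q = 0; q < nq; q++) {
      double u = -W / 2.0 + q * h;
      double t = 1.0 - std::pow(2.0 * u / W, 2);
      ku[q] = u;
      kv[q] = (t <= 0.0) ? ((t == 0.0) ? 1.0 : 0.0)
                         : R::bessel_i(beta * std::sqrt(t), 0.0, 1.0);
    }
    for (int x = 0; x < N; x++) {
      double f = (x - N / 2) / (double)G;  // cycles per grid sample
      double acc = 0.0;
      for (int q = 0; q < nq; q++) {
        double w = (q == 0 || q == nq - 1) ? 1.0 : ((q % 2) ? 4.0 : 2.0);
        acc += w * kv[q] * std::cos(2.0 * M_PI * f * ku[q]);
      }
      deapod[x] = acc * h / 3.0;
    }
  }

  inline double kb(double u) const {
    double au = std::fabs(u) / lut_step;
    int i = (int)au;
    if (i >= lut_n - 1) return 0.0;
    double f = au - i;
    return lut[i] * (1.0 - f) + lut[i + 1] * f;
  }

  // wrap a (possibly negative) grid index into [0, G)
  inline int wrap(int g) const {
    int r = g % G;
    return r < 0 ? r + G : r;
  }

  // k in cycles/pixel -> periodic grid coordinate in [0, G)
  inline double ucoord(double k) const {
    double v = k * G;
    double u = v - G * std::floor(v / G);
    return (u >= G) ? u - G : u;
  }
};

// image (N x N) -> oversampled k-space grid: deapodize, wrap-pad, FFT
inline arma::cx_mat img_to_grid(const arma::cx_mat& img, const GridPlan& P) {
  arma::cx_mat pad(P.G, P.G, arma::fill::zeros);
  for (int j = 0; j < P.N; j++) {
    int pj = P.wrap(j - P.N / 2);
    for (int i = 0; i < P.N; i++) {
      pad(P.wrap(i - P.N / 2), pj) = img(i, j) / (P.deapod[i] * P.deapod[j]);
    }
  }
  return arma::fft2(pad);
}

// adjoint of img_to_grid: unnormalized inverse FFT, crop, deapodize
inline arma::cx_mat grid_to_img(const arma::cx_mat& H, const GridPlan& P) {
  arma::cx_mat sp = arma::ifft2(H) * (double)(P.G) * (double)(P.G);
  arma::cx_mat out(P.N, P.N);
  for (int j = 0; j < P.N; j++) {
    int pj = P.wrap(j - P.N / 2);
    for (int i = 0; i < P.N; i++) {
      out(i, j) = sp(P.wrap(i - P.N / 2), pj) / (P.deapod[i] * P.deapod[j]);
    }
  }
  return out;
}

// separable kernel weights and wrapped indices for one sample
struct TapSet {
  int nt;                 // taps per dimension (W + 1)
  int ix[16], iy[16];
  double wx[16], wy[16];
};

inline void make_taps(double ux, double uy, const GridPlan& P, TapSet& T) {
  T.nt = P.W + 1;
  int gx0 = (int)std::ceil(ux - P.W / 2.0);
  int gy0 = (int)std::ceil(uy - P.W / 2.0);
  for (int t = 0; t < T.nt; t++) {
    T.ix[t] = P.wrap(gx0 + t);
    T.wx[t] = P.kb(ux - (gx0 + t));
    T.iy[t] = P.wrap(gy0 + t);
    T.wy[t] = P.kb(uy - (gy0 + t));
  }
}

inline arma::cx_double grid_interp(const arma::cx_mat& Fp, const TapSet& T) {
  arma::cx_double acc(0.0, 0.0);
  for (int b = 0; b < T.nt; b++) {
    if (T.wy[b] == 0.0) continue;
    arma::cx_double row(0.0, 0.0);
    const arma::cx_double* col = Fp.colptr(T.iy[b]);
    for (int a = 0; a < T.nt; a++) row += T.wx[a] * col[T.ix[a]];
    acc += T.wy[b] * row;
  }
  return acc;
}

inline void grid_spread(arma::cx_mat& H, arma::cx_double v, const TapSet& T) {
  for (int b = 0; b < T.nt; b++) {
    if (T.wy[b] == 0.0) continue;
    arma::cx_double vy = v * T.wy[b];
    arma::cx_double* col = H.colptr(T.iy[b]);
    for (int a = 0; a < T.nt; a++) col[T.ix[a]] += T.wx[a] * vy;
  }
}

// Rigid transform of an image: rotate by theta (radians) about the centre
// pixel (N/2, N/2), then translate by (tx, ty) pixels (first dim, second
// dim). Bilinear interpolation, zero outside. out(x) = in(R_{-theta}(x - t)).
inline arma::cx_mat rigid_transform(const arma::cx_mat& img, double tx,
                                    double ty, double theta) {
  int n1 = img.n_rows, n2 = img.n_cols;
  double c1 = n1 / 2, c2 = n2 / 2;
  double ct = std::cos(theta), st = std::sin(theta);
  arma::cx_mat out(n1, n2, arma::fill::zeros);
  for (int j = 0; j < n2; j++) {
    double yc = j - c2 - ty;
    for (int i = 0; i < n1; i++) {
      double xc = i - c1 - tx;
      double xs = ct * xc + st * yc + c1;
      double ys = -st * xc + ct * yc + c2;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 < 0 || y0 < 0 || x0 >= n1 - 1 || y0 >= n2 - 1) {
        // allow exact hits on the last row/col
        if (xs == n1 - 1 && y0 >= 0 && y0 < n2 - 1) { x0 = n1 - 2; }
        else if (ys == n2 - 1 && x0 >= 0 && x0 < n1 - 1) { y0 = n2 - 2; }
        else if (xs == n1 - 1 && ys == n2 - 1) { x0 = n1 - 2; y0 = n2 - 2; }
        else continue;
      }
      double fx = xs - x0, fy = ys - y0;
      out(i, j) = (1 - fx) * (1 - fy) * img(x0, y0) +
                  fx * (1 - fy) * img(x0 + 1, y0) +
                  (1 - fx) * fy * img(x0, y0 + 1) +
                  fx * fy * img(x0 + 1, y0 + 1);
    }
  }
  return out;
}
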
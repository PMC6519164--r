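// [[Rcpp::depends(RcppArmadillo)]]
#include "gridding.h"
using namespace arma;

// Joint-histogram normalized mutual information over the pixels where both
// images are valid (finite). Linear binning between each image's min and max
// over the shared mask. Returns (H(A)+H(B))/H(A,B) in [1, 2]; degenerate
// (constant) images return 1.
static double nmi_masked(const mat& a, const mat& b, int bins) {
  int n = a.n_elem;
  double amin = datum::inf, amax = -datum::inf;
  double bmin = datum::inf, bmax = -datum::inf;
  int m = 0;
  for (int i = 0; i < n; i++) {
    double av = a[i], bv = b[i];
    if (!std::isfinite(av) || !std::isfinite(bv)) continue;
    m++;
    if (av < amin) amin = av;
    if (av > amax) amax = av;
    if (bv < bmin) bmin = bv;
    if (bv > bmax) bmax = bv;
  }
  if (m == 0 || amax <= amin || bmax <= bmin) return 1.0;
  std::vector<double> joint((size_t)bins * bins, 0.0);
  double asc = bins / (amax - amin), bsc = bins / (bmax - bmin);
  for (int i = 0; i < n; i++) {
    double av = a[i], bv = b[i];
    if (!std::isfinite(av) || !std::isfinite(bv)) continue;
    int ia = (int)((av - amin) * asc);
    int ib = (int)((bv - bmin) * bsc);
    if (ia >= bins) ia = bins - 1;
    if (ib >= bins) ib = bins - 1;
    joint[(size_t)ib * bins + ia] += 1.0;
  }
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  double hab = 0.0;
  for (int ib = 0; ib < bins; ib++) {
    for (int ia = 0; ia < bins; ia++) {
      double p = joint[(size_t)ib * bins + ia] / m;
      if (p > 0) {
        hab -= p * std::log(p);
        pa[ia] += p;
        pb[ib] += p;
      }
    }
  }
  if (hab <= 0) return 1.0;
  double ha = 0.0, hb = 0.0;
  for (int i = 0; i < bins; i++) {
    if (pa[i] > 0) ha -= pa[i] * std::log(pa[i]);
    if (pb[i] > 0) hb -= pb[i] * std::log(pb[i]);
  }
  return (ha + hb) / hab;
}

// [[Rcpp::export]]
double cpp_nmi(const arma::mat& a, const arma::mat& b, int bins) {
  return nmi_masked(a, b, bins);
}

// transform the moving image, marking out-of-bounds pixels invalid (NaN)
static mat transform_masked(const mat& img, double tx, double ty, double th) {
  int n1 = img.n_rows, n2 = img.n_cols;
  double c1 = n1 / 2, c2 = n2 / 2;
  double ct = std::cos(th), st = std::sin(th);
  mat out(n1, n2);
  for (int j = 0; j < n2; j++) {
    double yc = j - c2 - ty;
    for (int i = 0; i < n1; i++) {
      double xc = i - c1 - tx;
      double xs = ct * xc + st * yc + c1;
      double ys = -st * xc + ct * yc + c2;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 < 0 || y0 < 0 || x0 >= n1 - 1 || y0 >= n2 - 1) {
        out(i, j) = datum::nan;
        continue;
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

// NMI between `fixed` and `moving` brought to pose (tx, ty, theta)
// [[Rcpp::export]]
double cpp_nmi_transformed(const arma::mat& fixed, const arma::mat& moving,
                           double tx, double ty, double theta, int bins) {
  return nmi_masked(fixed, transform_masked(moving, tx, ty, theta), bins);
}

// A constant, slightly off-grid "dither" pose is applied to both images
// before the joint histogram is formed. Without it, candidate poses that
// land on the pixel grid (notably the identity) skip interpolation
// smoothing entirely, denting the NMI landscape at exactly those poses and
// biasing the optimum by 1-3 degrees on streaky sliding-window images.
// Resampling both sides through a fixed off-grid pose makes the
// interpolation smoothing pose-independent while preserving the relative
// transform.
// [[Rcpp::export]]
arma::mat cpp_transform_masked(const arma::mat& img, double tx, double ty,
                               double theta) {
  return transform_masked(img, tx, ty, theta);
}

// NMI between dithered fixed image and moving at pose q composed with the
// same dither d: B = transform(moving, d o q).
// [[Rcpp::export]]
double cpp_nmi_dithered(const arma::mat& fixed_dithered, const arma::mat& moving,
                        double tx, double ty, double theta,
                        double dx, double dy, double dth, int bins) {
  double c = std::cos(dth), s = std::sin(dth);
  double qx = dx + c * tx - s * ty;
  double qy = dy + s * tx + c * ty;
  mat B = transform_masked(moving, qx, qy, dth + theta);
  return nmi_masked(fixed_dithered, B, bins);
}

// Exhaustive NMI evaluation over a (tx, ty, theta) grid with the dither
// pose applied to both sides; returns the best pose and its score. Used
// for the pyramid's seeding and local-refinement levels.
// [[Rcpp::export]]
arma::vec cpp_register_grid(const arma::mat& fixed, const arma::mat& moving,
                            const arma::vec& txs, const arma::vec& tys,
                            const arma::vec& thetas, double dx, double dy,
                            double dth, int bins) {
  mat A = transform_masked(fixed, dx, dy, dth);
  double best = -1.0;
  vec out(4, fill::zeros);
  for (unsigned k = 0; k < thetas.n_elem; k++) {
    for (unsigned j = 0; j < tys.n_elem; j++) {
      for (unsigned i = 0; i < txs.n_elem; i++) {
        double s = cpp_nmi_dithered(A, moving, txs[i], tys[j], thetas[k],
                                    dx, dy, dth, bins);
        if (s > best) {
          best = s;
          out[0] = txs[i]; out[1] = tys[j]; out[2] = thetas[k]; out[3] = s;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
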
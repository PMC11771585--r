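#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward non-uniform DFT of a weighted point set, sampled along radial
// spokes. Point j at pixel coordinates (x_j, y_j) with complex value v_j
// contributes v_j * exp(-i * k . r). Spoke i has angle alpha_i; its samples
// lie at k = t_m * (cos a, sin a) with t equally spaced (rad / pixel).
// Uses the projection recurrence: within a spoke the phase advances by a
// constant factor per sample, so only two complex exponentials per point and
// spoke are evaluated.
// Returns an n_spokes x n_samples complex matrix.
// [[Rcpp::export]]
arma::cx_mat spoke_dft_cpp(const arma::mat& xy, const arma::cx_vec& values,
                           const arma::vec& angles, const arma::vec& tvals) {
  const arma::uword m = xy.n_rows, ns = angles.n_elem, nt = tvals.n_elem;
  if (values.n_elem != m) stop("values must match point count");
  if (nt > 1) {
    const arma::vec dt = arma::diff(tvals);
    if (arma::abs(dt - dt(0)).max() > 1e-9)
      stop("tvals must be equally spaced");
  }
  const double t0 = tvals(0);
  const double step = nt > 1 ? tvals(1) - tvals(0) : 0.0;
  arma::cx_mat out(ns, nt, arma::fill::zeros);
  const std::complex<double> I(0.0, 1.0);
  for (arma::uword i = 0; i < ns; ++i) {
    const double ca = std::cos(angles(i)), sa = std::sin(angles(i));
    arma::vec u = xy.col(0) * ca + xy.col(1) * sa;   // projected coordinate
    arma::cx_vec acc = values % arma::exp(-I * (t0 * u));
    arma::cx_vec fac = arma::exp(-I * (step * u));
    for (arma::uword t = 0; t < nt; ++t) {
      out(i, t) = arma::accu(acc);
      if (t + 1 < nt) acc %= fac;
    }
  }
  return out;
}

// Adjoint non-uniform DFT onto an n x n pixel grid (coordinates centred,
// x = col - n/2, y = row - n/2, matching spoke_dft_cpp). data holds one
// (already density-weighted) complex value per k-point and channel; kx, ky
// give the k-space location (rad / pixel) of each point. The exp(i k . r)
// kernel separates into an x and a y phase vector per k-point, so each
// k-point costs one rank-1 outer-product update per channel.
// Returns an n x n x n_channels cube (row index = y, col index = x).
// [[Rcpp::export]]
arma::cx_cube spoke_adjoint_cpp(const arma::cx_mat& data, const arma::vec& kx,
                                const arma::vec& ky, int n) {
  const arma::uword nk = kx.n_elem, nch = data.n_cols;
  if (data.n_rows != nk) stop("data rows must match k-point count");
  arma::cx_cube img(n, n, nch, arma::fill::zeros);
  const std::complex<double> I(0.0, 1.0);
  arma::vec coord(n);
  for (int j = 0; j < n; ++j) coord(j) = j - n / 2;
  arma::cx_vec ey(n), ex(n);
  for (arma::uword p = 0; p < nk; ++p) {
    for (int j = 0; j < n; ++j) {
      ey(j) = std::polar(1.0, ky(p) * coord(j));
      ex(j) = std::polar(1.0, kx(p) * coord(j));
    }
    for (arma::uword c = 0; c < nch; ++c) {
      std::complex<double>* im = img.slice_memptr(c);
      const std::complex<double> w = data(p, c);
      for (int j = 0; j < n; ++j) {
        const std::complex<double> wx = w * ex(j);
        std::complex<double>* colp = im + (arma::uword)j * n;
        for (int i = 0; i < n; ++i) colp[i] += wx * ey(i);
      }
    }
  }
  return img;
}
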
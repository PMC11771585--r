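#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-axis EPG propagation over a compiled primitive-event table.
//
// The transverse configuration spectrum F(k), k in [-K, K], holds the
// Mx + i*My amplitude of configuration order k; Z(k) the longitudinal
// amplitudes, with the physical redundancy Z(-k) = conj(Z(k)) and the
// transverse conjugate counterpart F-(k) = conj(F(-k)) implicit.
//
// events: n x 5 matrix with columns kind, p1, p2, p3, p4:
//   kind 1 RF       p1 = flip (deg), p2 = phase (deg), p3 = B1-sensitive flag
//   kind 2 GRAD     p1 = integer configuration steps (single tracked axis)
//   kind 3 RELAX    p1 = dt (ms)
//   kind 4 ACQUIRE  p1 = demodulation phase (deg)
//   kind 5 CRUSH    (zero all transverse states; idealised break crusher)
//
// Returns the acquired complex samples, the final state and the total
// squared-magnitude truncation loss at the +/-K order boundary.
// [[Rcpp::export]]
List epg_run_cpp(const arma::mat& events, double t1, double t2,
                 double b1_scale, const std::complex<double>& rho,
                 double delta_f, int max_order) {
  const int K = max_order;
  const int n = 2 * K + 1;
  arma::cx_vec F(n, arma::fill::zeros);
  arma::cx_vec Z(n, arma::fill::zeros);
  Z(K) = 1.0;
  double dropped = 0.0;
  std::vector<std::complex<double>> sig;
  const std::complex<double> I(0.0, 1.0);
  const double d2r = arma::datum::pi / 180.0;

  for (arma::uword e = 0; e < events.n_rows; ++e) {
    const int kind = (int) events(e, 0);
    if (kind == 1) {                                   // RF rotation
      double flip = events(e, 1) * d2r;
      if (events(e, 3) > 0.5) flip *= b1_scale;
      const double phi = events(e, 2) * d2r;
      const double c2 = std::cos(flip / 2.0) * std::cos(flip / 2.0);
      const double s2 = std::sin(flip / 2.0) * std::sin(flip / 2.0);
      const double sa = std::sin(flip), ca = std::cos(flip);
      const std::complex<double> eip = std::exp(I * phi);
      const std::complex<double> eim = std::exp(-I * phi);
      const std::complex<double> e2p = eip * eip;
      arma::cx_vec Fc = arma::flipud(arma::conj(F));   // Fc(k) = conj(F(-k))
      arma::cx_vec Fn = c2 * F + s2 * e2p * Fc - I * eip * sa * Z;
      arma::cx_vec Zn = -0.5 * I * eim * sa * F + 0.5 * I * eip * sa * Fc
                        + ca * Z;
      F = Fn; Z = Zn;
    } else if (kind == 2) {                            // gradient shift
      const int steps = (int) events(e, 1);
      if (steps != 0) {
        arma::cx_vec Fn(n, arma::fill::zeros);
        for (int k = -K; k <= K; ++k) {
          const int src = k - steps;
          if (src >= -K && src <= K) Fn(k + K) = F(src + K);
        }
        // energy pushed beyond the tracked order window
        for (int k = -K; k <= K; ++k) {
          const int dst = k + steps;
          if (dst < -K || dst > K) dropped += std::norm(F(k + K));
        }
        F = Fn;
      }
    } else if (kind == 3) {                            // relaxation + off-res
      const double dt = events(e, 1);
      if (dt > 0.0) {
        const double e1 = std::exp(-dt / t1);
        const double e2 = std::exp(-dt / t2);
        const std::complex<double> ph =
          std::exp(-I * (2.0 * arma::datum::pi * delta_f * dt * 1e-3));
        F *= e2 * ph;
        Z *= e1;
        Z(K) += (1.0 - e1);
      }
    } else if (kind == 4) {                            // readout
      const double dem = events(e, 1) * d2r;
      sig.push_back(rho * F(K) * std::exp(-I * dem));
    } else if (kind == 5) {                            // break crusher
      F.zeros();
    }
  }

  return List::create(_["signal"] = sig, _["F"] = F, _["Z"] = Z,
                      _["dropped"] = dropped);
}
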
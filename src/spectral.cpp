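// Batch kernels for band-limited Gaussian synthesis and differential-entropy
// feature extraction. Filtering is zero-phase in the frequency domain: the
// spectrum is multiplied by the squared magnitude response of the band filter
// (computed in R from the Butterworth coefficients), which matches
// forward-backward time-domain filtering up to boundary transients.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double de_gauss(double var, double varfloor) {
  double v = var < varfloor ? varfloor : var;
  return 0.5 * std::log(2.0 * M_PI * M_E * v);
}

// raw: channels x samples; H2: samples x n_bands (real squared-magnitude
// response at each FFT bin); win: samples per window; returns channels x
// n_bands matrix of window-averaged differential entropies (nats).
// [[Rcpp::export]]
arma::mat de_extract_cpp(const arma::mat& raw, const arma::mat& H2,
                         const int win, const double varfloor) {
  const int ch = raw.n_rows, n = raw.n_cols, nb = H2.n_cols;
  const int nw = n / win;
  arma::mat out(ch, nb);
  arma::cx_mat Hc(H2, arma::mat(n, nb, arma::fill::zeros));
  for (int c = 0; c < ch; ++c) {
    arma::cx_vec S = arma::fft(raw.row(c).t());
    for (int b = 0; b < nb; ++b) {
      arma::vec y = arma::real(arma::ifft(arma::cx_vec(S % Hc.col(b))));
      double acc = 0.0;
      for (int w = 0; w < nw; ++w) {
        arma::vec seg = y.subvec(w * win, (w + 1) * win - 1);
        double m = arma::mean(seg);
        double v = arma::accu(arma::square(seg - m)) / (win - 1);
        acc += de_gauss(v, varfloor);
      }
      out(c, b) = acc / nw;
    }
  }
  return out;
}

// Draw one trial of band-limited Gaussian signals directly in the frequency
// domain. sigma: channels x n_bands target standard deviations; bins:
// n_bands x 2 (inclusive first/last positive-frequency FFT bin per band);
// n: samples. Uses the R RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat synth_trial_cpp(const arma::mat& sigma, const arma::imat& bins,
                          const int n) {
  const int ch = sigma.n_rows, nb = sigma.n_cols;
  arma::mat out(ch, n);
  for (int c = 0; c < ch; ++c) {
    arma::cx_vec S(n, arma::fill::zeros);
    for (int b = 0; b < nb; ++b) {
      const int k0 = bins(b, 0), k1 = bins(b, 1);
      const int m = k1 - k0 + 1;
      // each bin gets an independent complex unit normal scaled so the band
      // component has population variance sigma^2 per sample
      const double s = n * sigma(c, b) / (2.0 * std::sqrt((double) m));
      for (int k = k0; k <= k1; ++k) {
        const double re = norm_rand() * s, im = norm_rand() * s;
        S(k) = std::complex<double>(re, im);
        S(n - k) = std::complex<double>(re, -im);
      }
    }
    out.row(c) = arma::real(arma::ifft(S)).t();
  }
  return out;
}
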
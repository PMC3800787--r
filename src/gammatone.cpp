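#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Cascade of n first-order gammatone resonators realized as complex one-pole
// IIR sections. Each section has impulse response proportional to
// exp(-2*pi*bw*t) * exp(i*2*pi*cf*t); taking the real part at the end of the
// cascade gives the decaying-cosine gammatone response. Each section is
// normalized to unit magnitude response at cf, and the final real projection
// is doubled so a real tone at cf passes with gain ~1.
// [[Rcpp::export]]
NumericVector gammatone_cascade_cpp(NumericVector x, double cf, double bw,
                                    double fs, int n) {
  const double r = std::exp(-2.0 * M_PI * bw / fs);
  const double th = 2.0 * M_PI * cf / fs;
  const std::complex<double> p = std::polar(r, th);
  const std::complex<double> ecf = std::polar(1.0, -th);
  // per-section gain: unit response at the centre frequency
  const double g = std::abs(1.0 - p * ecf);

  const R_xlen_t len = x.size();
  std::vector<std::complex<double>> y(len);
  for (R_xlen_t k = 0; k < len; ++k) y[k] = x[k];

  for (int s = 0; s < n; ++s) {
    std::complex<double> prev(0.0, 0.0);
    for (R_xlen_t k = 0; k < len; ++k) {
      prev = g * y[k] + p * prev;
      y[k] = prev;
    }
  }

  NumericVector out(len);
  for (R_xlen_t k = 0; k < len; ++k) out[k] = 2.0 * y[k].real();
  return out;
}
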
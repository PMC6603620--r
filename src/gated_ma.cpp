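#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trailing (causal) outlier-gated moving average.
// For each index i, over the raw window of up to `window` trailing values:
// compute the window mean mu and population sd sigma, then average only the
// values with |p - mu| <= gate_k * sigma. If sigma == 0 (or nothing passes
// the gate, possible only for gate_k < 1) the whole window is averaged.
// [[Rcpp::export(name = ".gated_ma_cpp")]]
NumericVector gated_ma_cpp(NumericVector x, int window, double gate_k) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int s = i - window + 1;
    if (s < 0) s = 0;
    int len = i - s + 1;
    double sum = 0.0, sum2 = 0.0;
    for (int j = s; j <= i; ++j) {
      sum += x[j];
      sum2 += x[j] * x[j];
    }
    double mu = sum / len;
    double var = sum2 / len - mu * mu;
    if (var < 0) var = 0;
    double sigma = std::sqrt(var);
    if (sigma == 0.0) {
      out[i] = mu;
      continue;
    }
    double lim = gate_k * sigma;
    double gsum = 0.0;
    int gcount = 0;
    for (int j = s; j <= i; ++j) {
      if (std::fabs(x[j] - mu) <= lim) {
        gsum += x[j];
        ++gcount;
      }
    }
    out[i] = (gcount > 0) ? gsum / gcount : mu;
  }
  return out;
}
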
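#include <Rcpp.h>
using namespace Rcpp;

// One sequential scan of single-marker Gibbs updates for whole-genome
// regression. Maintains the residual e = y - mu - M beta in place.
//
// For marker k with prior beta_k ~ N(0, sigma2k[k]) (optionally a
// spike-slab with point mass at zero and inclusion probability prob_in),
// the full conditional is N(cxy / c, sigma2e / c) with
// c = x'x + sigma2e / sigma2k and cxy = x'(e + x beta_k).
//
// `resid`, `beta` and `delta` are modified in place; the caller owns them.
// [[Rcpp::export]]
void wgr_update_markers(const NumericMatrix& M, const NumericVector& xtx,
                        NumericVector resid, NumericVector beta,
                        IntegerVector delta, double sigma2e,
                        const NumericVector& sigma2k, double prob_in,
                        bool spike) {
  const int n = M.nrow(), p = M.ncol();
  for (int k = 0; k < p; ++k) {
    const double* x = &M(0, k);
    double s2k = sigma2k[k];
    if (s2k < 1e-12) s2k = 1e-12;
    double cxy = xtx[k] * beta[k];
    for (int i = 0; i < n; ++i) cxy += x[i] * resid[i];

    bool included = true;
    if (spike) {
      // log Bayes factor for inclusion, marginalizing beta_k
      double denom = s2k * xtx[k] + sigma2e;
      double logodds = std::log(prob_in / (1.0 - prob_in)) +
                       0.5 * std::log(sigma2e / denom) +
                       0.5 * cxy * cxy * s2k / (sigma2e * denom);
      double pin = (logodds > 35.0) ? 1.0
                   : (logodds < -35.0) ? 0.0
                   : 1.0 / (1.0 + std::exp(-logodds));
      included = unif_rand() < pin;
    }

    double newb = 0.0;
    if (included) {
      double c = xtx[k] + sigma2e / s2k;
      newb = R::rnorm(cxy / c, std::sqrt(sigma2e / c));
    }
    double diff = beta[k] - newb;
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) resid[i] += x[i] * diff;
    }
    beta[k] = newb;
    delta[k] = included ? 1 : 0;
  }
}
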
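#include <Rcpp.h>
using namespace Rcpp;

// Log likelihood of observed PIC counts under per-cell binomial capture
// thinning of a tabulated diploid pmf.
//
//   P(W_o = w_i | q_i) = sum_{k >= w_i} C(k, w_i) q_i^{w_i} (1-q_i)^{k-w_i} pd[k]
//
// The binomial terms are generated by the recurrence
//   b_{k+1} = b_k * (1 - q) * (k + 1) / (k + 1 - w),  b_w = q^w,
// which avoids per-term dbinom calls; this sits inside the innermost loop of
// the per-region likelihood-ratio test.
// [[Rcpp::export]]
double observed_loglik_cpp(IntegerVector w, NumericVector q, NumericVector pd) {
  const int C = w.size();
  const int K = pd.size();
  if (q.size() != C) stop("w and q must have the same length");
  double ll = 0.0;
  for (int i = 0; i < C; ++i) {
    const int wi = w[i];
    const double qi = q[i];
    double acc = 0.0;
    if (wi < K) {
      double b = std::pow(qi, wi);
      acc = b * pd[wi];
      for (int k = wi + 1; k < K; ++k) {
        b *= (1.0 - qi) * (double)k / (double)(k - wi);
        acc += b * pd[k];
      }
    }
    ll += std::log(acc > 1e-300 ? acc : 1e-300);
  }
  return ll;
}
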
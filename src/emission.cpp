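#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Batched log-emission computation over all windows, populations and copies.
//
// For PCR windows the member-marker allele probability is the crossover
// mixture f = cp * p + (1 - cp) * logit^{-1}(design %*% beta); for
// frequency-only windows it is the allele frequency alone. Missing member
// alleles contribute 0 to the log emission.
//
// design:   list over windows; NULL for frequency-only windows, else a list
//           of K (copies x m) matrices.
// memX:     list over windows of (copies x n_members) 0/1/NA matrices.
// p_mem:    list over windows of (n_members x K) allele-frequency matrices.
// freq_only: logical per window.
// beta:     list over windows; NULL or list of K (m x n_members) matrices.
// cp:       per-copy crossover probability of the support span.
//
// Returns a numeric array dim (copies, windows, K) of log emissions.
// [[Rcpp::export]]
NumericVector cpp_emission_loglik(List design, List memX, List p_mem,
                                  LogicalVector freq_only, List beta,
                                  NumericVector cp) {
  int J = memX.size();
  NumericMatrix X0 = memX[0];
  int C = X0.nrow();
  NumericMatrix p0 = p_mem[0];
  int K = p0.ncol();
  NumericVector out(C * J * K);
  out.attr("dim") = IntegerVector::create(C, J, K);
  const double lo = 1e-12, hi = 1.0 - 1e-12;

  for (int j = 0; j < J; ++j) {
    NumericMatrix X = memX[j];
    NumericMatrix P = p_mem[j];
    int nm = X.ncol();
    if (freq_only[j]) {
      for (int k = 0; k < K; ++k) {
        std::vector<double> lf(nm), l0(nm);
        for (int t = 0; t < nm; ++t) {
          double pk = std::min(std::max(P(t, k), lo), hi);
          lf[t] = std::log(pk); l0[t] = std::log1p(-pk);
        }
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int t = 0; t < nm; ++t) {
            double x = X(c, t);
            if (ISNAN(x)) continue;
            s += (x == 1.0) ? lf[t] : l0[t];
          }
          out[c + C * j + C * J * k] = s;
        }
      }
    } else {
      List Dk = design[j];
      List Bk = beta[j];
      for (int k = 0; k < K; ++k) {
        NumericMatrix D = Dk[k];
        NumericMatrix B = Bk[k];
        int m = D.ncol();
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          double cpc = cp[c];
          for (int t = 0; t < nm; ++t) {
            double x = X(c, t);
            if (ISNAN(x)) continue;
            double eta = 0.0;
            for (int r = 0; r < m; ++r) eta += D(c, r) * B(r, t);
            double q = 1.0 / (1.0 + std::exp(-eta));
            double f = cpc * P(t, k) + (1.0 - cpc) * q;
            f = std::min(std::max(f, lo), hi);
            s += (x == 1.0) ? std::log(f) : std::log1p(-f);
          }
          out[c + C * j + C * J * k] = s;
        }
      }
    }
  }
  return out;
}
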
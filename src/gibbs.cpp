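#include <Rcpp.h>
using namespace Rcpp;

// Poisson-Gamma Gibbs sweep loop. Each sweep: (a) multinomial allocation of
// every set's count across its member transcripts with probabilities
// proportional to the current mu; (b) conjugate Gamma redraw of every mu_t
// with shape alpha + sum_i X_it and rate beta + b * l_t (l in kb).
// Uses R's RNG so set.seed() in R fixes the chain.
// [[Rcpp::export]]
NumericMatrix cpp_gibbs(List set_members, NumericVector k, NumericVector mu0,
                        double b, NumericVector l_kb,
                        double alpha, double beta,
                        int iterations, int burn_in, int thin) {
  const int n_sets = set_members.size();
  const int n_t = mu0.size();
  const int n_keep = iterations / thin;

  std::vector<std::vector<int>> members(n_sets);
  int max_size = 1;
  for (int i = 0; i < n_sets; ++i) {
    IntegerVector m = set_members[i];
    members[i].assign(m.begin(), m.end());
    for (int &j : members[i]) j -= 1;  // to 0-based
    if ((int)members[i].size() > max_size) max_size = members[i].size();
  }

  NumericVector mu = clone(mu0);
  NumericMatrix out(n_keep, n_t);
  std::vector<double> xt(n_t), prob(max_size);
  std::vector<int> alloc(max_size);

  int kept = 0;
  const int total = burn_in + iterations;
  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(xt.begin(), xt.end(), 0.0);
    for (int i = 0; i < n_sets; ++i) {
      const std::vector<int> &m = members[i];
      const int sz = m.size();
      const int ki = (int)k[i];
      if (ki == 0) continue;
      if (sz == 1) { xt[m[0]] += ki; continue; }
      double tot = 0.0;
      for (int j = 0; j < sz; ++j) { prob[j] = mu[m[j]]; tot += prob[j]; }
      if (tot <= 0.0) {
        for (int j = 0; j < sz; ++j) prob[j] = 1.0 / sz;
      } else {
        for (int j = 0; j < sz; ++j) prob[j] /= tot;
      }
      rmultinom(ki, prob.data(), sz, alloc.data());
      for (int j = 0; j < sz; ++j) xt[m[j]] += alloc[j];
    }
    for (int t = 0; t < n_t; ++t) {
      mu[t] = R::rgamma(alpha + xt[t], 1.0 / (beta + b * l_kb[t]));
    }
    if (sweep >= burn_in && (sweep - burn_in) % thin == thin - 1) {
      if (kept < n_keep) {
        for (int t = 0; t < n_t; ++t) out(kept, t) = mu[t];
        ++kept;
      }
    }
    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
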
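#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the standard admixture model on biallelic diploid
// dosages. Latent variables: one cluster of origin per allele copy.
// Full conditionals:
//   z_copy | q, p  ~ Categorical( q[i,k] * p[k,l]^x (1-p[k,l])^(1-x) )
//   q_i | z        ~ Dirichlet(alpha + copy counts per cluster)
//   p_kl | z       ~ Beta(lambda + ref copies, lambda + alt copies)
// Heterozygotes contribute one ref and one alt copy, assigned
// independently; missing dosages (coded -1) are skipped. Uses R's RNG
// throughout so runs are reproducible under set.seed().

// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix geno, int K, double alpha, double lambda,
                     int n_burnin, int n_samples, int thin,
                     bool keep_q_samples) {
  const int N = geno.nrow(), L = geno.ncol();
  NumericMatrix q(N, K), p(K, L);
  NumericMatrix Qsum(N, K), Psum(K, L);
  const int n_ret = n_samples / thin;
  NumericVector loglik(n_ret);
  List q_samples(keep_q_samples ? n_ret : 0);

  // init: uniform ancestry, frequencies from the prior
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p(k, l) = R::rbeta(lambda, lambda);

  std::vector<double> w(K);
  std::vector<double> cnt(K);
  NumericMatrix refc(K, L), totc(K, L);

  int ret = 0;
  const int total = n_burnin + n_samples;
  for (int sweep = 1; sweep <= total; ++sweep) {
    std::fill(refc.begin(), refc.end(), 0.0);
    std::fill(totc.begin(), totc.end(), 0.0);

    for (int i = 0; i < N; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int l = 0; l < L; ++l) {
        const int g = geno(i, l);
        if (g < 0) continue;
        for (int copy = 0; copy < 2; ++copy) {
          const int x = (copy < g) ? 1 : 0;  // g ref copies, 2-g alt copies
          double wsum = 0.0;
          for (int k = 0; k < K; ++k) {
            const double pk = p(k, l);
            w[k] = q(i, k) * (x ? pk : 1.0 - pk);
            wsum += w[k];
          }
          int z = K - 1;
          if (wsum > 0.0) {
            double u = unif_rand() * wsum, acc = 0.0;
            for (int k = 0; k < K; ++k) {
              acc += w[k];
              if (u <= acc) { z = k; break; }
            }
          } else {
            z = (int)(unif_rand() * K);
            if (z == K) z = K - 1;
          }
          cnt[z] += 1.0;
          totc(z, l) += 1.0;
          if (x) refc(z, l) += 1.0;
        }
      }
      // q_i ~ Dirichlet(alpha + cnt)
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = R::rgamma(alpha + cnt[k], 1.0);
        gsum += w[k];
      }
      if (gsum <= 0.0) { std::fill(w.begin(), w.end(), 1.0); gsum = K; }
      for (int k = 0; k < K; ++k) q(i, k) = w[k] / gsum;
    }

    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        p(k, l) = R::rbeta(lambda + refc(k, l),
                           lambda + (totc(k, l) - refc(k, l)));

    if (sweep > n_burnin && (sweep - n_burnin) % thin == 0 && ret < n_ret) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i)
        for (int l = 0; l < L; ++l) {
          const int g = geno(i, l);
          if (g < 0) continue;
          double pr = 0.0;
          for (int k = 0; k < K; ++k) pr += q(i, k) * p(k, l);
          if (pr < 1e-12) pr = 1e-12;
          if (pr > 1.0 - 1e-12) pr = 1.0 - 1e-12;
          ll += g * std::log(pr) + (2 - g) * std::log(1.0 - pr);
          if (g == 1) ll += std::log(2.0);
        }
      loglik[ret] = ll;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += p(k, l);
      if (keep_q_samples) q_samples[ret] = clone(q);
      ++ret;
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= n_ret;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= n_ret;

  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["loglik_trace"] = loglik,
                      _["q_samples"] = q_samples);
}
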
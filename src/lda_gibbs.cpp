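// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// The sampler integrates out phi and theta and resamples each token's topic
// from the count-based conditional
//   p(z = k) ~ (n_kw + beta) / (n_k + V beta) * (n_jk + alpha),
// counts excluding the current token. Randomness comes from R's RNG so that
// set.seed() makes runs exactly reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// complete-data log likelihood log P(W|Z,beta) + log P(Z|alpha)
static double complete_loglik(const std::vector<int>& nkw,
                              const std::vector<int>& nk,
                              const std::vector<std::vector<int>>& njk,
                              const std::vector<size_t>& ndoc,
                              int K, int V, int M,
                              double alpha, double beta) {
  double Vb = V * beta, Ka = K * alpha;
  double ll = K * (R::lgammafn(Vb) - V * R::lgammafn(beta)) +
              M * (R::lgammafn(Ka) - K * R::lgammafn(alpha));
  const double lg_beta = R::lgammafn(beta);
  const double lg_alpha = R::lgammafn(alpha);
  for (int k = 0; k < K; ++k) {
    const int* row = &nkw[(size_t)k * V];
    for (int v = 0; v < V; ++v)
      ll += (row[v] == 0) ? lg_beta : R::lgammafn(row[v] + beta);
    ll -= R::lgammafn(nk[k] + Vb);
  }
  for (int j = 0; j < M; ++j) {
    for (int k = 0; k < K; ++k)
      ll += (njk[j][k] == 0) ? lg_alpha : R::lgammafn(njk[j][k] + alpha);
    ll -= R::lgammafn((double)ndoc[j] + Ka);
  }
  return ll;
}

// [[Rcpp::export(name = ".gibbs_lda_cpp")]]
List gibbs_lda_cpp(const List& docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in, int sample_every) {
  const int M = docs.size();
  std::vector<std::vector<int>> w(M);
  size_t T = 0;
  for (int j = 0; j < M; ++j) {
    IntegerVector d = docs[j];
    w[j].assign(d.begin(), d.end());  // 0-based word ids
    T += d.size();
  }

  std::vector<int> nkw((size_t)K * V, 0), nk(K, 0);
  std::vector<std::vector<int>> njk(M, std::vector<int>(K, 0));
  std::vector<std::vector<int>> z(M);
  std::vector<size_t> ndoc(M);

  RNGScope scope;
  for (int j = 0; j < M; ++j) {
    ndoc[j] = w[j].size();
    z[j].resize(ndoc[j]);
    for (size_t t = 0; t < ndoc[j]; ++t) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[j][t] = k;
      ++nkw[(size_t)k * V + w[j][t]];
      ++nk[k];
      ++njk[j][k];
    }
  }

  std::vector<double> probs(K);
  std::vector<double> ll_trace;
  std::vector<std::vector<double>> occ(M);
  for (int j = 0; j < M; ++j) occ[j].assign(ndoc[j] * (size_t)K, 0.0);
  std::vector<std::vector<int>> kept;
  const double Vb = V * beta;
  int n_keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < M; ++j) {
      std::vector<int>& zj = z[j];
      std::vector<int>& njkj = njk[j];
      const std::vector<int>& wj = w[j];
      for (size_t t = 0; t < wj.size(); ++t) {
        const int word = wj[t];
        const int kold = zj[t];
        --nkw[(size_t)kold * V + word];
        --nk[kold];
        --njkj[kold];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double p = (nkw[(size_t)k * V + word] + beta) / (nk[k] + Vb) *
                     (njkj[k] + alpha);
          probs[k] = p;
          tot += p;
        }
        double u = unif_rand() * tot, cum = 0.0;
        int knew = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += probs[k];
          if (u <= cum) { knew = k; break; }
        }
        zj[t] = knew;
        ++nkw[(size_t)knew * V + word];
        ++nk[knew];
        ++njkj[knew];
      }
    }
    if (it > burn_in) {
      ++n_keep;
      ll_trace.push_back(
          complete_loglik(nkw, nk, njk, ndoc, K, V, M, alpha, beta));
      for (int j = 0; j < M; ++j)
        for (size_t t = 0; t < ndoc[j]; ++t)
          occ[j][t * K + z[j][t]] += 1.0;
      if (sample_every > 0 && ((it - burn_in) % sample_every == 0)) {
        std::vector<int> flat;
        flat.reserve(T);
        for (int j = 0; j < M; ++j)
          flat.insert(flat.end(), z[j].begin(), z[j].end());
        kept.push_back(flat);
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix nkw_out(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkw_out(k, v) = nkw[(size_t)k * V + v];
  IntegerMatrix njk_out(M, K);
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < K; ++k) njk_out(j, k) = njk[j][k];
  List z_out(M), occ_out(M);
  for (int j = 0; j < M; ++j) {
    z_out[j] = IntegerVector(z[j].begin(), z[j].end());
    NumericMatrix m((int)ndoc[j], K);
    if (n_keep > 0)
      for (size_t t = 0; t < ndoc[j]; ++t)
        for (int k = 0; k < K; ++k) m((int)t, k) = occ[j][t * K + k] / n_keep;
    occ_out[j] = m;
  }
  List kept_out(kept.size());
  for (size_t s = 0; s < kept.size(); ++s)
    kept_out[s] = IntegerVector(kept[s].begin(), kept[s].end());

  return List::create(
      _["z"] = z_out, _["nkw"] = nkw_out, _["njk"] = njk_out,
      _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
      _["z_marginal"] = occ_out, _["z_samples"] = kept_out);
}
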
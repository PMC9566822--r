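#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampling for LDA.
//
// tokens: 0-based word ids, all documents concatenated
// doc:    0-based document id per token (non-decreasing not required)
// z_init: 0-based initial topic assignment per token
// Uses R's RNG (unif_rand), so a set.seed() on the R side makes the whole
// chain deterministic.
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector tokens, IntegerVector doc, int n_docs,
                   int K, int V, double alpha, double beta, int n_iter,
                   IntegerVector z_init) {
  const int N = tokens.size();
  IntegerVector z = clone(z_init);
  IntegerMatrix n_kw(K, V);
  IntegerMatrix n_dk(n_docs, K);
  IntegerVector n_k(K);

  for (int i = 0; i < N; ++i) {
    n_kw(z[i], tokens[i])++;
    n_dk(doc[i], z[i])++;
    n_k[z[i]]++;
  }

  std::vector<double> p(K);
  const double vbeta = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = tokens[i], d = doc[i];
      int k = z[i];
      n_kw(k, w)--; n_dk(d, k)--; n_k[k]--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (n_kw(kk, w) + beta) / (n_k[kk] + vbeta) * (n_dk(d, kk) + alpha);
        total += p[kk];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u < cum) { k = kk; break; }
      }
      z[i] = k;
      n_kw(k, w)++; n_dk(d, k)++; n_k[k]++;
    }
  }
  return List::create(_["z"] = z, _["n_kw"] = n_kw, _["n_dk"] = n_dk,
                      _["n_k"] = n_k);
}

// Fold-in Gibbs for held-out documents: the topic-word distributions (phi,
// K x V) stay fixed; only the per-document topic counts are resampled.
// Returns the final doc-topic count matrix (n_docs x K).
// [[Rcpp::export]]
IntegerMatrix gibbs_fold_in_cpp(IntegerVector tokens, IntegerVector doc,
                                int n_docs, NumericMatrix phi, double alpha,
                                int n_iter) {
  const int N = tokens.size();
  const int K = phi.nrow();
  IntegerVector z(N);
  IntegerMatrix m_dk(n_docs, K);
  std::vector<double> p(K);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    m_dk(doc[i], k)++;
  }
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = tokens[i], d = doc[i];
      int k = z[i];
      m_dk(d, k)--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = phi(kk, w) * (m_dk(d, kk) + alpha);
        total += p[kk];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u < cum) { k = kk; break; }
      }
      z[i] = k;
      m_dk(d, k)++;
    }
  }
  return m_dk;
}
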
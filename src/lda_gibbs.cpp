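// Collapsed Gibbs sampler for latent Dirichlet allocation.
// Uses R's RNG, so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double eta,
                   int iters, int burnin) {
  const int D = docs.size();
  std::vector< std::vector<int> > w(D), z(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
  }

  std::vector< std::vector<double> > nkw(K, std::vector<double>(V, 0.0));
  std::vector<double> nk(K, 0.0);
  std::vector< std::vector<double> > ndk(D, std::vector<double>(K, 0.0));

  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      nkw[k][w[d][i]] += 1.0; nk[k] += 1.0; ndk[d][k] += 1.0;
    }
  }

  NumericMatrix betaAcc(K, V), gammaAcc(D, K);
  int nSamples = 0;
  std::vector<double> prob(K);

  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int wi = w[d][i];
        const int zi = z[d][i];
        nkw[zi][wi] -= 1.0; nk[zi] -= 1.0; ndk[d][zi] -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = (nkw[k][wi] + eta) / (nk[k] + V * eta) *
                    (ndk[d][k] + alpha);
          tot += prob[k];
        }
        int kNew = K - 1;
        if (tot > 0.0) {
          double u = unif_rand() * tot, c = 0.0;
          for (int k = 0; k < K; ++k) {
            c += prob[k];
            if (u <= c) { kNew = k; break; }
          }
        }
        z[d][i] = kNew;
        nkw[kNew][wi] += 1.0; nk[kNew] += 1.0; ndk[d][kNew] += 1.0;
      }
    }
    if (it >= burnin) {
      ++nSamples;
      for (int k = 0; k < K; ++k) {
        const double den = nk[k] + V * eta;
        for (int v = 0; v < V; ++v)
          betaAcc(k, v) += (den > 0.0 ? (nkw[k][v] + eta) / den : 1.0 / V);
      }
      for (int d = 0; d < D; ++d) {
        double nd = 0.0;
        for (int k = 0; k < K; ++k) nd += ndk[d][k];
        const double den = nd + K * alpha;
        for (int k = 0; k < K; ++k)
          gammaAcc(d, k) += (den > 0.0 ? (ndk[d][k] + alpha) / den : 1.0 / K);
      }
    }
  }

  if (nSamples > 0) {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) betaAcc(k, v) /= nSamples;
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) gammaAcc(d, k) /= nSamples;
  }
  return List::create(_["beta"] = betaAcc, _["gamma"] = gammaAcc);
}
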
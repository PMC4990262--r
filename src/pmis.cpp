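#include <Rcpp.h>
using namespace Rcpp;

// Accumulate, over all clustering iterations, the misclassified-spike
// counts |mis_n(Ci,Cj)| between every pair of clusters.
//
// labels:  G x Nite matrix of ensemble labels per signature group (1-based)
// sizes:   spike count of each signature group (length G)
// assign:  cluster id per signature group, 1..C (0 = excluded)
// nClusters: C
//
// Per iteration n and ensemble cluster k, with M[i][k] the number of
// spikes of cluster i landing in k: the side with the strictly smaller
// (nonzero) intersection counts as misclassified; ties count neither.
// Returns a C x C symmetric matrix of summed counts (zero diagonal); the
// caller normalizes by (N_i + N_j) * Nite.
// [[Rcpp::export]]
NumericMatrix pmisCounts(IntegerMatrix labels, IntegerVector sizes,
                         IntegerVector assign, int nClusters) {
  const int G = labels.nrow();
  const int Nite = labels.ncol();
  NumericMatrix out(nClusters, nClusters);
  int Kmax = 0;
  for (int g = 0; g < G; ++g)
    for (int n = 0; n < Nite; ++n)
      if (labels(g, n) > Kmax) Kmax = labels(g, n);
  std::vector<double> M((size_t)nClusters * Kmax);
  std::vector<int> touched;
  touched.reserve((size_t)nClusters * 4);
  for (int n = 0; n < Nite; ++n) {
    std::fill(M.begin(), M.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      int c = assign[g];
      if (c <= 0) continue;
      int k = labels(g, n) - 1;
      M[(size_t)(c - 1) * Kmax + k] += sizes[g];
    }
    for (int k = 0; k < Kmax; ++k) {
      touched.clear();
      for (int c = 0; c < nClusters; ++c)
        if (M[(size_t)c * Kmax + k] > 0) touched.push_back(c);
      const int m = (int)touched.size();
      for (int a = 0; a < m; ++a) {
        double va = M[(size_t)touched[a] * Kmax + k];
        for (int b = a + 1; b < m; ++b) {
          double vb = M[(size_t)touched[b] * Kmax + k];
          if (va == vb) continue;  // strict inequality: ties count neither
          double add = va < vb ? va : vb;
          out(touched[a], touched[b]) += add;
          out(touched[b], touched[a]) += add;
        }
      }
    }
  }
  return out;
}
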
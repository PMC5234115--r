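#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for source apportionment of one sink sample.
//
// Each sink read i carries a latent source label z_i in {1..V, Unknown}.
// Known-source likelihoods are computed from the fixed pooled source count
// matrix with a symmetric Dirichlet smoothing alpha1; the Unknown source's
// likelihood uses the counts of sink reads currently assigned to it with
// smoothing alpha2; the assignment prior is (n_v^{-i} + beta). Restarts are
// independent chains; after `burnin` full sweeps one draw of the mixing
// proportions n_v/N is recorded, then `ndraws - 1` further draws separated
// by `delay` sweeps. Uses R's RNG, so set.seed() in R governs the result.
//
// sink: length-T count vector; src: V x T pooled source counts.
// Returns (restarts * ndraws) x (V + 1) matrix of proportions, Unknown last.
// [[Rcpp::export]]
NumericMatrix gibbs_sink_cpp(IntegerVector sink, NumericMatrix src,
                             double alpha1, double alpha2, double beta,
                             int restarts, int burnin, int ndraws, int delay) {
  const int T = sink.size();
  const int V = src.nrow();
  if (src.ncol() != T) stop("source matrix and sink disagree on OTU count");

  // expand sink into individual reads
  long N = 0;
  for (int t = 0; t < T; ++t) N += sink[t];
  if (N <= 0) stop("sink has zero reads");
  std::vector<int> taxon(N);
  {
    long k = 0;
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < sink[t]; ++c) taxon[k++] = t;
  }

  // fixed per-taxon likelihood under each known source
  std::vector<double> like(static_cast<size_t>(V) * T);
  for (int v = 0; v < V; ++v) {
    double tot = 0;
    for (int t = 0; t < T; ++t) tot += src(v, t);
    const double denom = tot + T * alpha1;
    for (int t = 0; t < T; ++t)
      like[static_cast<size_t>(v) * T + t] = (src(v, t) + alpha1) / denom;
  }

  NumericMatrix out(restarts * ndraws, V + 1);
  std::vector<double> w(V + 1);
  std::vector<int> z(N), nv(V + 1), unk(T);

  for (int r = 0; r < restarts; ++r) {
    std::fill(nv.begin(), nv.end(), 0);
    std::fill(unk.begin(), unk.end(), 0);
    for (long i = 0; i < N; ++i) {
      int v = static_cast<int>(unif_rand() * (V + 1));
      if (v > V) v = V;
      z[i] = v;
      nv[v]++;
      if (v == V) unk[taxon[i]]++;
    }
    int recorded = 0;
    int sweep = 0;
    while (recorded < ndraws) {
      // one full sweep
      for (long i = 0; i < N; ++i) {
        const int t = taxon[i];
        const int zi = z[i];
        nv[zi]--;
        if (zi == V) unk[t]--;
        double tot = 0;
        for (int v = 0; v < V; ++v) {
          w[v] = like[static_cast<size_t>(v) * T + t] * (nv[v] + beta);
          tot += w[v];
        }
        const double nu = nv[V];
        w[V] = ((unk[t] + alpha2) / (nu + T * alpha2)) * (nu + beta);
        tot += w[V];
        double u = unif_rand() * tot;
        int v = 0;
        for (; v < V; ++v) {
          u -= w[v];
          if (u <= 0) break;
        }
        z[i] = v;
        nv[v]++;
        if (v == V) unk[t]++;
      }
      ++sweep;
      bool record = false;
      if (recorded == 0) record = (sweep >= burnin + 1);
      else record = ((sweep - burnin - 1) % delay == 0);
      if (record) {
        const int row = r * ndraws + recorded;
        for (int v = 0; v <= V; ++v)
          out(row, v) = static_cast<double>(nv[v]) / static_cast<double>(N);
        ++recorded;
      }
    }
  }
  return out;
}
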
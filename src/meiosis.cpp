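#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Simulate gametes for a set of meioses under the Haldane model: per
// chromosome the crossover count is Poisson with mean equal to the genetic
// length (marker span) in Morgans, crossover positions are uniform in
// genetic (cM) coordinates, and the starting phase is a fair coin. Uses the
// R RNG, so set.seed() upstream makes results reproducible.
//
// Matrices are marker-major (m x n_individuals): an individual's genome is
// one contiguous column, which keeps the marker walk cache-friendly.
//
// hap1, hap2 : m x n_ind integer matrices of allele codes (0/1)
// parent_idx : 1-based column index of the parent for each gamete
// cM         : per-marker genetic position (within-chromosome scale)
// starts     : 0-based offset of each chromosome's first marker
// counts     : markers per chromosome
// returns    : list(gametes = m x n_gamete matrix,
//                   crossovers = nchrom x n_gamete matrix)
// [[Rcpp::export]]
List sim_gametes_cpp(const IntegerMatrix& hap1,
                     const IntegerMatrix& hap2,
                     const IntegerVector& parent_idx,
                     const NumericVector& cM,
                     const IntegerVector& starts,
                     const IntegerVector& counts) {
  const int m = hap1.nrow();
  const int ng = parent_idx.size();
  const int nchrom = starts.size();
  IntegerMatrix out(m, ng);
  IntegerMatrix nxo_out(nchrom, ng);
  std::vector<double> xo;
  for (int g = 0; g < ng; ++g) {
    const int p = parent_idx[g] - 1;
    const int* h1 = &hap1(0, p);
    const int* h2 = &hap2(0, p);
    int* o = &out(0, g);
    for (int c = 0; c < nchrom; ++c) {
      const int s = starts[c], k = counts[c];
      if (k == 0) continue;
      const double lo = cM[s], hi = cM[s + k - 1];
      const double morgans = (hi - lo) / 100.0;
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int nxo = (morgans > 0) ? (int) R::rpois(morgans) : 0;
      nxo_out(c, g) = nxo;
      if (nxo == 0) {
        std::copy(phase ? h2 + s : h1 + s,
                  phase ? h2 + s + k : h1 + s + k, o + s);
        continue;
      }
      xo.resize(nxo);
      for (int i = 0; i < nxo; ++i) xo[i] = lo + unif_rand() * (hi - lo);
      std::sort(xo.begin(), xo.end());
      int next = 0;
      for (int j = 0; j < k; ++j) {
        while (next < nxo && xo[next] <= cM[s + j]) { phase ^= 1; ++next; }
        o[s + j] = phase ? h2[s + j] : h1[s + j];
      }
    }
  }
  return List::create(_["gametes"] = out, _["crossovers"] = nxo_out);
}
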
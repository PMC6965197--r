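#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch gamete assembly for the forward simulators.
//
// HT holds phased haplotypes in loci-major layout: column 2i-1 and 2i
// (1-based) are the two haplotypes of diploid individual i, so every
// haplotype is contiguous in memory. For every entry p of `parent` one
// recombinant gamete is drawn from individual p: crossover count is
// Poisson on the genome-wide Morgan length, crossover positions are
// uniform on the cumulative Morgan scale (cum_m, strictly increasing
// across chromosomes), and each chromosome starts from a randomly chosen
// parental haplotype (independent assortment). Crossover segments are
// copied with std::copy, so the per-gamete cost is a few contiguous
// block copies. Uses R's RNG: results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gametes_cpp(const IntegerMatrix& HT,
                          const IntegerVector& parent,
                          const NumericVector& cum_m,
                          const IntegerVector& chr_starts,
                          double total_morgans) {
  const int S = HT.nrow();
  const int n_out = parent.size();
  const int n_chr = chr_starts.size();

  IntegerMatrix out(S, n_out);
  std::vector<double> cuts;
  std::vector<int> toggles;

  for (int g = 0; g < n_out; ++g) {
    const int* src[2];
    src[0] = &HT(0, 2 * parent[g] - 2);
    src[1] = &HT(0, 2 * parent[g] - 1);
    int* dst = &out(0, g);

    int k = (int) R::rpois(total_morgans);
    cuts.clear();
    for (int c = 0; c < k; ++c) cuts.push_back(unif_rand() * total_morgans);
    std::sort(cuts.begin(), cuts.end());
    // first locus index at or after each crossover
    toggles.clear();
    for (int c = 0; c < k; ++c) {
      int idx = (int) (std::lower_bound(cum_m.begin(), cum_m.end(),
                                        cuts[c]) - cum_m.begin());
      if (idx < S) toggles.push_back(idx);
    }
    std::size_t tp = 0;
    for (int c = 0; c < n_chr; ++c) {
      int a = chr_starts[c] - 1;
      const int chr_end = (c + 1 < n_chr) ? chr_starts[c + 1] - 1 : S;
      int phase = (unif_rand() < 0.5) ? 1 : 0;
      // crossovers that fell before this chromosome's first locus have no
      // observable effect (the phase is freshly randomised anyway)
      while (tp < toggles.size() && toggles[tp] <= a) {
        phase ^= 1;
        ++tp;
      }
      while (a < chr_end) {
        int b = chr_end;
        if (tp < toggles.size() && toggles[tp] < chr_end) {
          b = toggles[tp];
          ++tp;
        }
        std::copy(src[phase] + a, src[phase] + b, dst + a);
        phase ^= 1;
        a = b;
      }
    }
  }
  return out;
}
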
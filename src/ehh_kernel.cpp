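#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-directional EHH curve by incremental group refinement: at each flanking
// SNP the carrier set is partitioned by extended haplotype identity and
// EHH = sum_h C(n_h,2) / C(n,2). Stops at the first node below the cutoff
// (kept as the final node) or at the end of the site set (truncated = true).
// core and carriers are 1-based indices from R.
// [[Rcpp::export(name = ".ehh_curve_kernel")]]
List ehh_curve_kernel(const IntegerMatrix& alleles,
                      const IntegerVector& positions, int core,
                      const IntegerVector& carriers, bool right,
                      double cutoff) {
  const int n = carriers.size();
  const int S = alleles.ncol();
  const double pairs_total = n * (n - 1) / 2.0;
  // EHH(0) = 1 by definition: haplotype identity is counted over the
  // extension away from the core, the core allele being shared by
  // construction of an allele-class carrier set (population-level carrier
  // sets inherit the same convention, so their curves also start at 1).
  std::vector<double> offsets(1, 0.0), ehh(1, 1.0);
  std::vector<int> g(n, 0), newg(n), sizes;
  bool truncated = false;
  const int step = right ? 1 : -1;
  int s = core - 1 + step;
  if (s < 0 || s >= S) truncated = true;
  while (s >= 0 && s < S) {
    std::unordered_map<long long, int> remap;
    remap.reserve(2 * n);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
      long long key = 2LL * g[i] + alleles(carriers[i] - 1, s);
      auto it = remap.find(key);
      if (it == remap.end()) {
        remap.emplace(key, ng);
        newg[i] = ng++;
      } else {
        newg[i] = it->second;
      }
    }
    sizes.assign(ng, 0);
    for (int i = 0; i < n; ++i) sizes[newg[i]]++;
    double hom = 0.0;
    for (int c : sizes) hom += c * (c - 1) / 2.0;
    const double e = hom / pairs_total;
    g = newg;
    offsets.push_back(std::abs(static_cast<double>(positions[s]) -
                               positions[core - 1]));
    ehh.push_back(e);
    if (e < cutoff) break;
    if ((right && s == S - 1) || (!right && s == 0)) {
      truncated = true;
      break;
    }
    s += step;
  }
  return List::create(_["offsets"] = wrap(offsets),
                      _["ehh_values"] = wrap(ehh),
                      _["truncated"] = truncated);
}
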
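#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch meiosis for one chromosome over a pool of haplotypes.
//
// The pool is a ragged array: haplotype h (0-based) owns segments
// [off[h], off[h+1]) of `ends`/`keys`; segment i covers
// [previous end, ends[i]) in 0-based half-open bp coordinates and carries an
// integer founder key. Each gamete g recombines pool haplotypes hapA[g] and
// hapB[g]; hapB[g] < 0 requests intact transmission of hapA[g] (male X).
//
// Crossover count ~ Poisson(morgans); positions uniform in genetic distance
// (constant cM/Mb, hence uniform in bp, rounded to integer bp and
// deduplicated); the starting parental phase is a fair coin. All randomness
// goes through R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gamete_batch_cpp(IntegerVector ends, IntegerVector keys, IntegerVector off,
                      IntegerVector hapA, IntegerVector hapB,
                      double length_bp, double morgans) {
  const int ng = hapA.size();
  if (hapB.size() != ng) stop("hapA and hapB must have equal length");
  const int L = (int)length_bp;
  if (L <= 0) stop("chromosome length must be positive");

  std::vector<int> oe, ok;
  oe.reserve(ends.size() > 64 ? ends.size() : 64);
  ok.reserve(ends.size() > 64 ? ends.size() : 64);
  IntegerVector ooff(ng + 1), nxo(ng);
  std::vector<int> xo;

  for (int g = 0; g < ng; ++g) {
    ooff[g] = (int)oe.size();
    const int ha = hapA[g], hb = hapB[g];
    if (ha < 0 || ha + 1 >= off.size() || off[ha] == off[ha + 1])
      stop("invalid or empty parental haplotype index");

    int k = 0;
    if (hb >= 0 && morgans > 0.0) k = (int)R::rpois(morgans);

    if (hb < 0 || k == 0) {
      // intact copy of one parental haplotype
      int src = ha;
      if (hb >= 0 && unif_rand() < 0.5) src = hb;
      for (int i = off[src]; i < off[src + 1]; ++i) {
        oe.push_back(ends[i]);
        ok.push_back(keys[i]);
      }
      nxo[g] = 0;
      continue;
    }

    xo.clear();
    for (int i = 0; i < k; ++i) {
      int p = 1 + (int)(unif_rand() * (double)(L - 1));
      if (p >= L) p = L - 1;
      xo.push_back(p);
    }
    std::sort(xo.begin(), xo.end());
    xo.erase(std::unique(xo.begin(), xo.end()), xo.end());
    k = (int)xo.size();
    nxo[g] = k;

    int cur = (unif_rand() < 0.5) ? 0 : 1; // 0 -> hapA, 1 -> hapB
    int pa = off[ha], pb = off[hb];
    int a = 0;
    const size_t out0 = oe.size();
    for (int seg = 0; seg <= k; ++seg) {
      const int b = (seg < k) ? xo[seg] : L;
      const int hap = cur ? hb : ha;
      int &ptr = cur ? pb : pa;
      while (ptr < off[hap + 1] && ends[ptr] <= a) ++ptr;
      int p = ptr;
      while (p < off[hap + 1]) {
        const int e = ends[p] < b ? ends[p] : b;
        const int kk = keys[p];
        if (oe.size() > out0 && ok.back() == kk) {
          oe.back() = e; // contiguous same-key pieces merge
        } else {
          oe.push_back(e);
          ok.push_back(kk);
        }
        if (ends[p] >= b) break;
        ++p;
      }
      a = b;
      cur = 1 - cur;
    }
  }
  ooff[ng] = (int)oe.size();
  return List::create(_["ends"] = wrap(oe), _["keys"] = wrap(ok),
                      _["off"] = ooff, _["nxo"] = nxo);
}
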
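#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Apply the nanopore-like error model to each sequence, base by base:
// 1. delete the base with probability p_del, scaled by
//    hp_del_multiplier * (run_length - 1) when the base sits inside a
//    homopolymer run of length >= 2 (probability capped just below 1);
// 2. otherwise emit it, substituted with probability p_sub (uniform over the
//    other three bases);
// 3. then insert one uniform random base after it with probability p_ins.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double p_sub,
                                double p_ins, double p_del, double hp_mult) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  std::vector<int> run;
  for (int s = 0; s < n; ++s) {
    const char* x = CHAR(STRING_ELT(seqs, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    // run length of the maximal homopolymer containing each position
    run.assign(len, 1);
    int i = 0;
    while (i < len) {
      int j = i;
      while (j + 1 < len && x[j + 1] == x[i]) ++j;
      int rl = j - i + 1;
      for (int k = i; k <= j; ++k) run[k] = rl;
      i = j + 1;
    }
    buf.clear();
    buf.reserve(len + 8);
    for (i = 0; i < len; ++i) {
      double pd = (run[i] >= 2) ? p_del * hp_mult * (run[i] - 1) : p_del;
      if (pd > 0.999) pd = 0.999;
      if (unif_rand() < pd) continue;  // base dropped
      char b = x[i];
      if (p_sub > 0 && unif_rand() < p_sub) {
        // substitute with one of the other three bases
        int r = (int)(unif_rand() * 3.0); if (r > 2) r = 2;
        int k = 0;
        for (int t = 0; t < 4; ++t) {
          if (BASES[t] == b) continue;
          if (k == r) { b = BASES[t]; break; }
          ++k;
        }
      }
      buf.push_back(b);
      if (p_ins > 0 && unif_rand() < p_ins) {
        int r = (int)(unif_rand() * 4.0); if (r > 3) r = 3;
        buf.push_back(BASES[r]);
      }
    }
    out[s] = buf;
  }
  return out;
}
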
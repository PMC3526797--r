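// Exhaustive single-gap alignment oracle: enumerates every start position on
// both strands, every single reference-deletion placement (length 1..max) and
// every 3' clip length.  No seeding, no banding -- used as an independent
// reference for validating the seed-and-extend aligner.

#include <Rcpp.h>
#include <algorithm>
#include <string>
using namespace Rcpp;

static char cbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export]]
IntegerVector oracle_align_cpp(CharacterVector reads, CharacterVector ref_seqs,
                               int match = 1, int mismatch = -2, int gap = 3,
                               int max_del_event = 3) {
  std::vector<std::string> strands;
  for (int i = 0; i < ref_seqs.size(); ++i) {
    std::string fw = as<std::string>(ref_seqs[i]);
    std::string rc(fw.rbegin(), fw.rend());
    for (auto& c : rc) c = cbase(c);
    strands.push_back(fw);
    strands.push_back(rc);
  }
  const int NEG = -100000000;
  IntegerVector out(reads.size(), NA_INTEGER);
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string r = as<std::string>(reads[ri]);
    const int L = (int)r.size();
    int best = NEG;
    std::vector<int> cum0(L + 1), cumd(L + 1);
    for (const auto& S : strands) {
      const int G = (int)S.size();
      for (int s = 0; s < G; ++s) {
        cum0[0] = 0;
        int reach0 = L; // read bases placeable without a gap
        for (int i = 0; i < L; ++i) {
          if (s + i >= G) { reach0 = i; break; }
          int sc = (r[i] == S[s + i] && r[i] != 'N') ? match : mismatch;
          cum0[i + 1] = cum0[i] + sc;
        }
        for (int i = 1; i <= reach0; ++i) best = std::max(best, cum0[i]);
        for (int d = 1; d <= max_del_event; ++d) {
          cumd[0] = 0;
          int reachd = L; // placeable with the reference shifted by d
          for (int i = 0; i < L; ++i) {
            if (s + i + d >= G) { reachd = i; break; }
            int sc = (r[i] == S[s + i + d] && r[i] != 'N') ? match : mismatch;
            cumd[i + 1] = cumd[i] + sc;
          }
          // gap after j consumed bases (j >= 1), resume at j+1, clip at m
          int sufmax = NEG;
          for (int j = reachd - 1; j >= 1; --j) {
            sufmax = std::max(sufmax, cumd[j + 1]);
            if (j <= reach0 && sufmax > NEG) {
              best = std::max(best, cum0[j] + (sufmax - cumd[j]) - gap);
            }
          }
        }
      }
    }
    if (best > NEG) out[ri] = best;
  }
  return out;
}
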
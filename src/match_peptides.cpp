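#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Exact multi-pattern substring search: for each protein sequence, every
// occurrence of every peptide is reported. One pass over the proteome per
// distinct peptide length, with a hash lookup per window, so overlapping and
// repeated occurrences are all found.
//
// Returns a list of integer vectors: peptide index, protein index, and
// 0-based start position (all 1-based indices for R except the start).
// [[Rcpp::export(rng = false)]]
List cpp_match_peptides(CharacterVector proteins, CharacterVector peptides) {
  // group peptide indices by length
  std::unordered_map<int, std::unordered_map<std::string, std::vector<int> > > by_len;
  for (int i = 0; i < peptides.size(); ++i) {
    std::string p = as<std::string>(peptides[i]);
    by_len[(int)p.size()][p].push_back(i + 1);
  }
  std::vector<int> pep_idx, prot_idx, start0;
  for (int j = 0; j < proteins.size(); ++j) {
    std::string s = as<std::string>(proteins[j]);
    int n = (int)s.size();
    for (auto& lp : by_len) {
      int L = lp.first;
      if (L > n) continue;
      auto& dict = lp.second;
      std::string window;
      for (int pos = 0; pos + L <= n; ++pos) {
        window.assign(s, pos, L);
        auto hit = dict.find(window);
        if (hit != dict.end()) {
          for (int id : hit->second) {
            pep_idx.push_back(id);
            prot_idx.push_back(j + 1);
            start0.push_back(pos);
          }
        }
      }
    }
  }
  return List::create(_["peptide"] = wrap(pep_idx),
                      _["protein"] = wrap(prot_idx),
                      _["start"] = wrap(start0));
}
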
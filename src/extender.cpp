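#include <Rcpp.h>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

std::string revcomp_str(const char *s, int n);

// Greedy seed extension over end-k-mer hash tables.
//
// Two tables map the k-mer at each live seed end to the seed holding it.
// For every read (in list order, `cycles` full passes, the scan pointer
// never resets after an extension) the read's two end k-mers are looked up:
//   read 3'-end k-mer in the 5' table  -> extend that seed 5'-ward by the
//     read's leading non-overlapping bases;
//   read 5'-end k-mer in the 3' table  -> extend 3'-ward by the trailing bases;
// then the same two lookups with the reverse complement. First hit wins and
// a read triggers at most one extension per encounter. After an extension the
// consumed key is removed and the new end k-mer inserted; if the new key is
// already present that end is frozen (key not inserted, bases kept).
//
// Initial end k-mers must be unique per table: a later seed whose end k-mer
// duplicates an earlier key is dropped from extension entirely.
// [[Rcpp::export(name = ".extender_run_cpp")]]
List extender_run_cpp(CharacterVector seeds, int k, CharacterVector reads,
                      int cycles) {
  int ns = seeds.size();
  std::vector<std::string> seq(ns);
  std::vector<bool> dropped(ns, false), frozen5(ns, false), frozen3(ns, false);
  IntegerVector ext5(ns), ext3(ns);
  std::unordered_map<std::string, int> five, three;
  five.reserve(ns * 2); three.reserve(ns * 2);

  for (int s = 0; s < ns; ++s) {
    seq[s] = std::string(CHAR(seeds[s]));
    int L = seq[s].size();
    if (L < k) stop("seed %d is shorter than k", s + 1);
    std::string k5 = seq[s].substr(0, k), k3 = seq[s].substr(L - k);
    if (five.count(k5) || three.count(k3)) { dropped[s] = true; continue; }
    five[k5] = s; three[k3] = s;
  }

  R_xlen_t nr = reads.size();
  for (int cycle = 0; cycle < cycles; ++cycle) {
    for (R_xlen_t r = 0; r < nr; ++r) {
      const char *rs = CHAR(reads[r]);
      int L = std::strlen(rs);
      if (L <= k) continue;  // equal to k: zero non-overlapping bases
      bool done = false;
      std::string fwd(rs, L);
      for (int orient = 0; orient < 2 && !done; ++orient) {
        std::string rc;
        const std::string *use = &fwd;
        if (orient == 1) { rc = revcomp_str(rs, L); use = &rc; }
        // read 3'-end k-mer against 5' table: leftward extension
        {
          auto it = five.find(use->substr(L - k));
          if (it != five.end()) {
            int s = it->second;
            seq[s] = use->substr(0, L - k) + seq[s];
            ext5[s] += L - k;
            five.erase(it);
            std::string nk = seq[s].substr(0, k);
            if (five.count(nk)) frozen5[s] = true; else five[nk] = s;
            done = true;
            continue;
          }
        }
        // read 5'-end k-mer against 3' table: rightward extension
        {
          auto it = three.find(use->substr(0, k));
          if (it != three.end()) {
            int s = it->second;
            seq[s] += use->substr(k);
            ext3[s] += L - k;
            three.erase(it);
            std::string nk = seq[s].substr(seq[s].size() - k);
            if (three.count(nk)) frozen3[s] = true; else three[nk] = s;
            done = true;
          }
        }
      }
    }
  }

  CharacterVector out(ns);
  LogicalVector drp(ns), fr5(ns), fr3(ns);
  for (int s = 0; s < ns; ++s) {
    out[s] = seq[s]; drp[s] = dropped[s];
    fr5[s] = frozen5[s]; fr3[s] = frozen3[s];
  }
  return List::create(_["sequence"] = out, _["extended_5p"] = ext5,
                      _["extended_3p"] = ext3, _["dropped"] = drp,
                      _["frozen_5p"] = fr5, _["frozen_3p"] = fr3,
                      _["live_keys_5p"] = (int)five.size(),
                      _["live_keys_3p"] = (int)three.size());
}
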
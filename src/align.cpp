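#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <limits>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const int BIG = std::numeric_limits<int>::max() / 4;

// Affine-gap global alignment (Gotoh), minimizing cost:
// match 0 (N never matches), mismatch `mismatch`, gap of length g costs
// gap_open + g * gap_extend. Deterministic traceback: on ties prefer the
// diagonal, then a gap in b (consuming a), then a gap in a.
// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("global_align: sequences must be non-empty");
  size_t W = (size_t)(m + 1);
  std::vector<int> M((n + 1) * W, BIG), X((n + 1) * W, BIG), Y((n + 1) * W, BIG);
  // traceback: predecessor matrix id (0=M,1=X,2=Y), per matrix
  std::vector<uint8_t> tM((n + 1) * W), tX((n + 1) * W), tY((n + 1) * W);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    tX[i * W] = 1;
  }
  tX[1 * W] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1);
      size_t u = (i - 1) * W + j, l = i * W + (j - 1);
      bool eq = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      int sub = eq ? match : mismatch;
      // M: prefer M, X, Y on ties
      int best = M[d]; uint8_t t = 0;
      if (X[d] < best) { best = X[d]; t = 1; }
      if (Y[d] < best) { best = Y[d]; t = 2; }
      M[c] = (best >= BIG) ? BIG : best + sub; tM[c] = t;
      // X: gap in b, consumes a[i-1]
      best = M[u] + gap_open; t = 0;
      if (X[u] < best) { best = X[u]; t = 1; }
      if (Y[u] + gap_open < best) { best = Y[u] + gap_open; t = 2; }
      X[c] = (best >= BIG) ? BIG : best + gap_extend; tX[c] = t;
      // Y: gap in a, consumes b[j-1]
      best = M[l] + gap_open; t = 0;
      if (X[l] + gap_open < best) { best = X[l] + gap_open; t = 1; }
      if (Y[l] < best) { best = Y[l]; t = 2; }
      Y[c] = (best >= BIG) ? BIG : best + gap_extend; tY[c] = t;
    }
  }
  size_t e = (size_t)n * W + m;
  int cur = 0, score = M[e];
  if (X[e] < score) { score = X[e]; cur = 1; }
  if (Y[e] < score) { score = Y[e]; cur = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (cur == 0) {
      uint8_t t = tM[c];
      ra.push_back(a[--i]); rb.push_back(b[--j]);
      cur = t;
    } else if (cur == 1) {
      uint8_t t = tX[c];
      ra.push_back(a[--i]); rb.push_back('-');
      cur = t;
    } else {
      uint8_t t = tY[c];
      ra.push_back('-'); rb.push_back(b[--j]);
      cur = t;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0, mism = 0;
  std::vector<int> run_seq, run_start, run_len;
  int cols = ra.size();
  for (int c0 = 0; c0 < cols; ++c0) {
    char ca = ra[c0], cb = rb[c0];
    if (ca == '-' || cb == '-') {
      int which = (ca == '-') ? 0 : 1;  // 0: gap in a, 1: gap in b
      if (!run_seq.empty() && run_seq.back() == which &&
          run_start.back() + run_len.back() == c0) {
        run_len.back()++;
      } else {
        run_seq.push_back(which); run_start.push_back(c0); run_len.push_back(1);
      }
    } else if (ca == cb && ca != 'N') {
      ++matches;
    } else {
      ++mism;
    }
  }
  CharacterVector gseq(run_seq.size());
  for (size_t q = 0; q < run_seq.size(); ++q) gseq[q] = run_seq[q] == 0 ? "a" : "b";
  return List::create(
    _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = score,
    _["matches"] = matches, _["mismatches"] = mism,
    _["gap_runs"] = DataFrame::create(
      _["sequence"] = gseq,
      _["start"] = IntegerVector(run_start.begin(), run_start.end()),
      _["length"] = IntegerVector(run_len.begin(), run_len.end())));
}

static inline int base2bit(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// Semi-global (read global, reference local) banded alignment around a
// diagonal; returns the match count of the best alignment. Unit edit costs.
static int banded_matches(const char *rd, int lr, const char *rf, int lf,
                          int diag, int band) {
  int lo_ref = std::max(0, diag - band);
  int hi_ref = std::min(lf, diag + lr + band);
  int w = hi_ref - lo_ref;
  if (w <= 0) return 0;
  // DP over read i (0..lr) x window j (0..w); free end gaps in reference.
  std::vector<int> cost((lr + 1) * (w + 1), BIG), mat((lr + 1) * (w + 1), 0);
  for (int j = 0; j <= w; ++j) cost[j] = 0;  // free leading ref
  for (int i = 1; i <= lr; ++i) cost[i * (w + 1)] = i;
  for (int i = 1; i <= lr; ++i) {
    for (int j = 1; j <= w; ++j) {
      size_t c = (size_t)i * (w + 1) + j;
      char cr = rd[i - 1], cf = rf[lo_ref + j - 1];
      bool eq = cr == cf && cr != 'N';
      int best = cost[c - (w + 1) - 1] + (eq ? 0 : 1);
      int bm = mat[c - (w + 1) - 1] + (eq ? 1 : 0);
      int alt = cost[c - (w + 1)] + 1;  // gap in ref (read base unaligned)
      if (alt < best) { best = alt; bm = mat[c - (w + 1)]; }
      alt = cost[c - 1] + 1;            // gap in read
      if (alt < best) { best = alt; bm = mat[c - 1]; }
      cost[c] = best; mat[c] = bm;
    }
  }
  int best = BIG, bm = 0;
  for (int j = 0; j <= w; ++j) {  // free trailing ref
    size_t c = (size_t)lr * (w + 1) + j;
    if (cost[c] < best || (cost[c] == best && mat[c] > bm)) {
      best = cost[c]; bm = mat[c];
    }
  }
  return bm;
}

// Assign reads to reference transcripts: shared-k-mer prefilter, ungapped
// identity on the best shared diagonal, banded semi-global rescue for
// candidates below threshold. Identity = matches / read length. Ties across
// clusters -> ambiguous; ties within one cluster -> assigned to the cluster.
// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(CharacterVector reads, CharacterVector refs,
                      IntegerVector ref_cluster, int kmer, double min_identity,
                      int band) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int r = 0; r < nref; ++r) R[r] = std::string(CHAR(refs[r]));
  // k-mer index (2-bit packed); k-mers containing N are skipped
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;
  uint64_t mask = (kmer >= 32) ? ~0ULL : ((1ULL << (2 * kmer)) - 1);
  if (kmer > 32) stop("kmer must be <= 32");
  for (int r = 0; r < nref; ++r) {
    const std::string &s = R[r];
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2bit(s[p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | b) & mask;
      if (++run >= kmer) idx[h].push_back(std::make_pair(r, p - kmer + 1));
    }
  }

  R_xlen_t nr = reads.size();
  IntegerVector best_ref(nr), n_matches(nr), assigned_cluster(nr);
  NumericVector identity(nr);
  std::unordered_map<int64_t, int> votes;
  for (R_xlen_t i = 0; i < nr; ++i) {
    const char *rd = CHAR(reads[i]);
    int lr = std::strlen(rd);
    votes.clear();
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < lr; ++p) {
      int b = base2bit(rd[p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | b) & mask;
      if (++run >= kmer) {
        auto it = idx.find(h);
        if (it == idx.end()) continue;
        for (auto &pr : it->second) {
          int diag = pr.second - (p - kmer + 1);
          votes[((int64_t)pr.first << 32) | (uint32_t)(diag + 1000000)]++;
        }
      }
    }
    // best diagonal per reference
    std::unordered_map<int, std::pair<int, int> > bydiag;  // ref -> (diag, votes)
    for (auto &kv : votes) {
      int r = (int)(kv.first >> 32);
      int diag = (int)(uint32_t)(kv.first & 0xffffffff) - 1000000;
      auto it = bydiag.find(r);
      if (it == bydiag.end() || kv.second > it->second.second)
        bydiag[r] = std::make_pair(diag, kv.second);
    }
    int bestm = -1, bref = -1, nt = 0; bool multi_cluster = false; int bclus = -1;
    for (auto &kv : bydiag) {
      int r = kv.first, diag = kv.second.first;
      const std::string &rf = R[r];
      int lf = rf.size(), m = 0;
      for (int p = 0; p < lr; ++p) {
        int q = p + diag;
        if (q < 0 || q >= lf) continue;
        if (rd[p] == rf[q] && rd[p] != 'N') ++m;
      }
      if (m < lr && (double)m / lr < min_identity) {
        // gapped rescue only if plausibly related
        if ((double)m / lr >= 0.5)
          m = banded_matches(rd, lr, rf.c_str(), lf, diag, band);
      }
      if (m > bestm) {
        bestm = m; bref = r; nt = 1;
        bclus = ref_cluster[r]; multi_cluster = false;
      } else if (m == bestm && m >= 0) {
        ++nt;
        if (ref_cluster[r] != bclus) multi_cluster = true;
      }
    }
    double id = (bestm < 0) ? 0.0 : (double)bestm / lr;
    identity[i] = id; n_matches[i] = bestm < 0 ? 0 : bestm;
    if (bestm < 0 || id < min_identity) {
      best_ref[i] = NA_INTEGER; assigned_cluster[i] = NA_INTEGER;  // unassigned
    } else if (multi_cluster) {
      best_ref[i] = bref + 1; assigned_cluster[i] = -1;            // ambiguous
    } else {
      best_ref[i] = bref + 1; assigned_cluster[i] = bclus;
    }
  }
  return List::create(_["best_ref"] = best_ref, _["identity"] = identity,
                      _["cluster"] = assigned_cluster);
}
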
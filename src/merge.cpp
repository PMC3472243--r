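#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

static const double LOG_Q = std::log(0.25);   // per-site chance match
static const double LOG_1MQ = std::log(0.75);

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'N': return 'N';
  default: return 0;
  }
}

std::string revcomp_str(const char *s, int n) {
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i) {
    char c = comp_base(s[n - 1 - i]);
    if (c == 0) stop("reverse_complement: invalid base '%c'", s[n - 1 - i]);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(x[i]);
    out[i] = revcomp_str(s, (int)std::strlen(s));
  }
  return out;
}

// [[Rcpp::export(name = ".min_qual_cpp")]]
IntegerVector min_qual_cpp(CharacterVector qual) {
  R_xlen_t n = qual.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *q = CHAR(qual[i]);
    int m = 1000;
    for (const char *p = q; *p; ++p) if (*p - 33 < m) m = *p - 33;
    out[i] = (m == 1000) ? NA_INTEGER : m;
  }
  return out;
}

// log P(k | n) under the null of random 25% per-site matching
static inline double log_binom_p(int k, int n) {
  return R::lchoose((double)n, (double)k) + k * LOG_Q + (n - k) * LOG_1MQ;
}

// cached log factorials for the batch path
static std::vector<double> lfact_tab;
static void ensure_lfact(int n) {
  if ((int)lfact_tab.size() >= n + 1) return;
  int old = lfact_tab.size();
  lfact_tab.resize(n + 1);
  if (old == 0) { lfact_tab[0] = 0.0; old = 1; }
  for (int i = old; i <= n; ++i) lfact_tab[i] = lfact_tab[i - 1] + std::log((double)i);
}
static inline double log_binom_p_fast(int k, int n) {
  return lfact_tab[n] - lfact_tab[k] - lfact_tab[n - k] + k * LOG_Q +
         (n - k) * LOG_1MQ;
}

// Count matches for every relative offset of read1 against revcomp(read2).
// Candidates are indexed by implied fragment length f in [1, l1+l2-1]:
// rc2 starts at offset f-l2 relative to read1; overlap n(f) = min(l1,l2,f,l1+l2-f).
// [[Rcpp::export(name = ".overlap_counts_cpp")]]
DataFrame overlap_counts_cpp(std::string seq1, std::string seq2) {
  int l1 = seq1.size(), l2 = seq2.size();
  if (l1 == 0 || l2 == 0) stop("both mates must be non-empty");
  std::string rc2 = revcomp_str(seq2.c_str(), l2);
  int nf = l1 + l2 - 1;
  IntegerVector frag(nf), nn(nf), kk(nf);
  for (int f = 1; f <= nf; ++f) {
    int off = f - l2;
    int lo = off > 0 ? off : 0;
    int hi = std::min(l1, f);
    int n = hi - lo, k = 0;
    for (int i = lo; i < hi; ++i) {
      char c1 = seq1[i], c2 = rc2[i - off];
      if (c1 == c2 && c1 != 'N') ++k;
    }
    frag[f - 1] = f; nn[f - 1] = n; kk[f - 1] = k;
  }
  return DataFrame::create(_["fragment"] = frag, _["n"] = nn, _["k"] = kk);
}

struct MergeOut {
  bool accepted;
  int reason;     // 0 ok, 1 p_too_large, 2 ratio_too_small, 3 no_candidate
  int fragment, n, k;
  double best_lp, second_lp;
};

static MergeOut score_pair(const char *s1, int l1, const std::string &rc2, int l2,
                           double log_p_thr, double log_ratio, int min_overlap) {
  MergeOut o; o.accepted = false; o.reason = 3; o.fragment = NA_INTEGER;
  o.n = 0; o.k = 0;
  o.best_lp = std::numeric_limits<double>::infinity();
  o.second_lp = std::numeric_limits<double>::infinity();
  int nf = l1 + l2 - 1;
  for (int f = 1; f <= nf; ++f) {
    int off = f - l2;
    int lo = off > 0 ? off : 0;
    int hi = std::min(l1, f);
    int n = hi - lo;
    if (n < min_overlap) continue;
    const char *p1 = s1 + lo;
    const char *p2 = rc2.data() + (lo - off);
    int k = 0;
    for (int i = 0; i < n; ++i)
      k += (p1[i] == p2[i]) & (p1[i] != 'N');
    double lp = log_binom_p_fast(k, n);
    if (lp < o.best_lp) {
      o.second_lp = o.best_lp;
      o.best_lp = lp; o.fragment = f; o.n = n; o.k = k;
    } else if (lp < o.second_lp) {
      o.second_lp = lp;
    }
  }
  if (o.fragment == NA_INTEGER) { o.reason = 3; return o; }
  if (!(o.best_lp < log_p_thr)) { o.reason = 1; return o; }
  if (!(o.second_lp >= o.best_lp + log_ratio)) { o.reason = 2; return o; }
  o.accepted = true; o.reason = 0;
  return o;
}

// Combine one overlap column; returns base, writes quality into *q.
static inline char combine_col(char c1, int q1, char c2, int q2, int cap, int *q) {
  if (c1 == 'N' && c2 == 'N') { *q = 0; return 'N'; }
  if (c1 == 'N') { *q = q2; return c2; }
  if (c2 == 'N') { *q = q1; return c1; }
  if (c1 == c2) { *q = std::min(q1 + q2, cap); return c1; }
  if (q1 > q2) { *q = q1 - q2; return c1; }
  if (q2 > q1) { *q = q2 - q1; return c2; }
  *q = 0; return c1;
}

// Batch merger. Qualities are phred+33 strings.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     double p_threshold, double ratio_threshold,
                     int min_overlap, int quality_cap) {
  R_xlen_t np = seq1.size();
  if (qual1.size() != np || seq2.size() != np || qual2.size() != np)
    stop("mate vectors must have equal length");
  double log_p_thr = std::log(p_threshold);
  double log_ratio = std::log(ratio_threshold);
  {
    int maxn = 1;
    for (R_xlen_t i = 0; i < np; ++i) {
      int l = std::strlen(CHAR(seq1[i])); if (l > maxn) maxn = l;
      l = std::strlen(CHAR(seq2[i])); if (l > maxn) maxn = l;
    }
    ensure_lfact(maxn);
  }
  CharacterVector mseq(np), mqual(np);
  LogicalVector accepted(np);
  IntegerVector reason(np), overlap_n(np), fragment(np), trimmed1(np), trimmed2(np);
  NumericVector best_p(np), second_p(np);
  double qual_sum = 0; R_xlen_t qual_n = 0;

  for (R_xlen_t i = 0; i < np; ++i) {
    const char *s1 = CHAR(seq1[i]); int l1 = std::strlen(s1);
    const char *s2 = CHAR(seq2[i]); int l2 = std::strlen(s2);
    const char *q1 = CHAR(qual1[i]); const char *q2 = CHAR(qual2[i]);
    if ((int)std::strlen(q1) != l1 || (int)std::strlen(q2) != l2)
      stop("sequence/quality length mismatch at pair %d", (int)(i + 1));
    std::string rc2 = revcomp_str(s2, l2);
    MergeOut o = score_pair(s1, l1, rc2, l2, log_p_thr, log_ratio, min_overlap);
    accepted[i] = o.accepted; reason[i] = o.reason;
    best_p[i] = std::isfinite(o.best_lp) ? std::exp(o.best_lp) : NA_REAL;
    second_p[i] = std::isfinite(o.second_lp) ? std::exp(o.second_lp) : NA_REAL;
    if (!o.accepted) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap_n[i] = NA_INTEGER; fragment[i] = NA_INTEGER;
      trimmed1[i] = NA_INTEGER; trimmed2[i] = NA_INTEGER;
      continue;
    }
    int f = o.fragment, off = f - l2;
    std::string ms(f, 'N'), mq(f, '!');
    for (int p = 0; p < f; ++p) {
      bool h1 = p < l1;
      int j = p - off;
      bool h2 = j >= 0 && j < l2;
      char base; int q;
      if (h1 && h2) {
        base = combine_col(s1[p], q1[p] - 33, rc2[j], q2[l2 - 1 - j] - 33,
                           quality_cap, &q);
      } else if (h1) {
        base = s1[p]; q = q1[p] - 33;
      } else {
        base = rc2[j]; q = q2[l2 - 1 - j] - 33;
      }
      ms[p] = base;
      mq[p] = (char)(std::min(q, 93) + 33);
      qual_sum += q; ++qual_n;
    }
    mseq[i] = ms; mqual[i] = mq;
    overlap_n[i] = o.n; fragment[i] = f;
    trimmed1[i] = std::max(0, l1 - f);
    trimmed2[i] = std::max(0, l2 - f);
  }
  return List::create(
    _["seq"] = mseq, _["qual"] = mqual, _["accepted"] = accepted,
    _["reason"] = reason, _["overlap_n"] = overlap_n, _["fragment"] = fragment,
    _["trimmed1"] = trimmed1, _["trimmed2"] = trimmed2,
    _["best_p"] = best_p, _["second_p"] = second_p,
    _["mean_quality"] = qual_n ? qual_sum / qual_n : NA_REAL);
}
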
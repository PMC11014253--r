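#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Integer alphabet shared with the R side:
//   0 '$' terminal sentinel, 1 '!' inter-strand sentinel,
//   2 A, 3 C, 4 G, 5 T, 6 X (N / contig junction, never matched),
//   7 pattern-only "never matches" code for read Ns.
static const int NSYM = 7;

// Suffix array by prefix doubling, O(n log^2 n); robust on repetitive text.
// [[Rcpp::export]]
IntegerVector build_sa_cpp(IntegerVector text) {
  int n = text.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = text[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = (a + k < n) ? rnk[a + k] : -1;
      int rb = (b + k < n) ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return wrap(sa); // 0-based suffix start positions
}

// Occurrence checkpoints every k positions: row r holds counts of each
// symbol in bwt[0 .. r*k-1].
// [[Rcpp::export]]
IntegerMatrix occ_build_cpp(IntegerVector bwt, int k) {
  int n = bwt.size();
  int nchk = n / k + 1;
  IntegerMatrix occ(nchk, NSYM);
  std::vector<int> cnt(NSYM, 0);
  for (int i = 0; i <= n; ++i) {
    if (i % k == 0) {
      int r = i / k;
      if (r < nchk) for (int c = 0; c < NSYM; ++c) occ(r, c) = cnt[c];
    }
    if (i < n) cnt[bwt[i]]++;
  }
  return occ;
}

static inline int occf(const IntegerMatrix &occ, const IntegerVector &bwt,
                       int k, int c, int i) {
  int r = i / k;
  int cnt = occ(r, c);
  for (int j = r * k; j < i; ++j) if (bwt[j] == c) cnt++;
  return cnt;
}

// Backward search for the whole pattern; returns (lo, hi, matched_len).
// lo >= hi encodes the empty interval.
// [[Rcpp::export]]
IntegerVector backward_search_cpp(IntegerVector bwt, IntegerMatrix occ,
                                  IntegerVector C, int k,
                                  IntegerVector pattern) {
  int n = bwt.size();
  int lo = 0, hi = n, matched = 0;
  for (int t = pattern.size() - 1; t >= 0; --t) {
    int c = pattern[t];
    int nlo = 0, nhi = 0;
    if (c >= 0 && c < NSYM) {
      nlo = C[c] + occf(occ, bwt, k, c, lo);
      nhi = C[c] + occf(occ, bwt, k, c, hi);
    }
    if (nlo >= nhi) return IntegerVector::create(0, 0, matched);
    lo = nlo; hi = nhi; matched++;
  }
  return IntegerVector::create(lo, hi, matched);
}

static int locate_row(const IntegerVector &bwt, const IntegerMatrix &occ,
                      const IntegerVector &C, int k,
                      const IntegerVector &sa_sample, int r) {
  int steps = 0;
  while (sa_sample[r] < 0) {
    int c = bwt[r];
    r = C[c] + occf(occ, bwt, k, c, r);
    steps++;
  }
  return sa_sample[r] + steps;
}

// Resolve suffix-array rows [lo, hi) to text positions via LF-walking to the
// nearest sampled row; truncated at max_hits.
// [[Rcpp::export]]
List locate_cpp(IntegerVector bwt, IntegerMatrix occ, IntegerVector C, int k,
                IntegerVector sa_sample, int lo, int hi, int max_hits) {
  std::vector<int> out;
  bool truncated = false;
  for (int r = lo; r < hi; ++r) {
    if ((int)out.size() >= max_hits) { truncated = true; break; }
    out.push_back(locate_row(bwt, occ, C, k, sa_sample, r));
  }
  return List::create(_["positions"] = wrap(out), _["truncated"] = truncated);
}

// Greedy maximal-suffix seeding: repeatedly take the longest exact suffix
// match ending at the current cursor, record its occurrences if it reaches
// min_len, and restart left of it. Returns one row per located occurrence:
// (read_offset0, length, text_pos0).
// [[Rcpp::export]]
List fm_seeds_cpp(IntegerVector bwt, IntegerMatrix occ, IntegerVector C, int k,
                  IntegerVector sa_sample, IntegerVector pattern,
                  int min_len, int max_locate) {
  int n = bwt.size();
  int m = pattern.size();
  std::vector<int> offs, lens, poss;
  bool truncated = false;
  int end = m;
  while (end >= min_len) {
    int lo = 0, hi = n, len = 0;
    for (int t = end - 1; t >= 0; --t) {
      int c = pattern[t];
      int nlo = 0, nhi = 0;
      if (c >= 0 && c < NSYM) {
        nlo = C[c] + occf(occ, bwt, k, c, lo);
        nhi = C[c] + occf(occ, bwt, k, c, hi);
      }
      if (nlo >= nhi) break;
      lo = nlo; hi = nhi; len++;
    }
    int start = end - len;
    if (len >= min_len) {
      int cnt = 0;
      for (int r = lo; r < hi; ++r) {
        if (cnt >= max_locate) { truncated = true; break; }
        offs.push_back(start);
        lens.push_back(len);
        poss.push_back(locate_row(bwt, occ, C, k, sa_sample, r));
        cnt++;
      }
      end = start;
    } else {
      end = end - 1;
    }
  }
  return List::create(_["read_offset"] = wrap(offs), _["length"] = wrap(lens),
                      _["text_pos"] = wrap(poss), _["truncated"] = truncated);
}
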
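#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Base codes: 2 A, 3 C, 4 G, 5 T; 6/7 are N-like and score 0.
// cls 0: C->T conversion strand (ref C / read T scores as a match)
// cls 1: G->A conversion strand (ref G / read A scores as a match)
static inline int subst(int r, int q, int cls, int match, int mismatch) {
  if (r >= 6 || q >= 6 || r < 2 || q < 2) return 0;
  if (r == q) return match;
  if (cls == 0 && r == 3 && q == 5) return match;
  if (cls == 1 && r == 4 && q == 2) return match;
  return -mismatch;
}

// Banded local alignment with affine gaps (cost of a k-gap = open + k*ext)
// under the conversion-asymmetric substitution score. The band is centred
// on the seed diagonal: only cells with |j - i - diag0| <= band are filled.
// Returns the optimum with a traceback suitable for CIGAR construction.
// [[Rcpp::export]]
List banded_sw_cpp(IntegerVector ref, IntegerVector read, int cls,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int band, int diag0) {
  const int m = read.size(), w = ref.size();
  const int NEG = -1000000000;
  // full (m+1) x (w+1) matrices; desk-scale windows only
  std::vector<int> H((m + 1) * (w + 1), NEG), E((m + 1) * (w + 1), NEG),
      F((m + 1) * (w + 1), NEG);
  auto at = [&](int i, int j) { return i * (w + 1) + j; };
  for (int j = 0; j <= w; ++j) H[at(0, j)] = 0;
  for (int i = 0; i <= m; ++i) H[at(i, 0)] = 0;

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + diag0 - band);
    int jhi = std::min(w, i + diag0 + band);
    for (int j = jlo; j <= jhi; ++j) {
      int hup = H[at(i - 1, j)], eup = E[at(i - 1, j)];
      int e = NEG;
      if (hup > NEG) e = hup - gap_open - gap_ext;
      if (eup > NEG) e = std::max(e, eup - gap_ext);
      E[at(i, j)] = e;
      int hlf = H[at(i, j - 1)], flf = F[at(i, j - 1)];
      int f = NEG;
      if (hlf > NEG) f = hlf - gap_open - gap_ext;
      if (flf > NEG) f = std::max(f, flf - gap_ext);
      F[at(i, j)] = f;
      int hdg = H[at(i - 1, j - 1)];
      int h = 0;
      if (hdg > NEG) h = std::max(h, hdg + subst(ref[j - 1], read[i - 1], cls,
                                                match, mismatch));
      h = std::max(h, std::max(e, f));
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["aligned"] = false);
  }

  // traceback
  std::vector<char> ops;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (insertion), 2 = F (deletion)
  int mm = 0, conv = 0, indel = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int s = subst(ref[j - 1], read[i - 1], cls, match, mismatch);
      if (H[at(i - 1, j - 1)] > (-1000000000) && h == H[at(i - 1, j - 1)] + s) {
        ops.push_back('M');
        int r = ref[j - 1], q = read[i - 1];
        if (r >= 2 && r <= 5 && q >= 2 && q <= 5 && r != q) {
          bool isconv = (cls == 0 && r == 3 && q == 5) ||
                        (cls == 1 && r == 4 && q == 2);
          if (isconv) conv++; else mm++;
        }
        i--; j--;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back('I'); indel++;
      int e = E[at(i, j)];
      if (E[at(i - 1, j)] > (-1000000000) && e == E[at(i - 1, j)] - gap_ext)
        { i--; }
      else { i--; state = 0; }
    } else {
      ops.push_back('D'); indel++;
      int f = F[at(i, j)];
      if (F[at(i, j - 1)] > (-1000000000) && f == F[at(i, j - 1)] - gap_ext)
        { j--; }
      else { j--; state = 0; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length the ops
  std::vector<int> lens; std::vector<char> kinds;
  for (char op : ops) {
    if (!kinds.empty() && kinds.back() == op) lens.back()++;
    else { kinds.push_back(op); lens.push_back(1); }
  }
  CharacterVector kv(kinds.size());
  for (size_t t = 0; t < kinds.size(); ++t) kv[t] = std::string(1, kinds[t]);
  return List::create(
      _["score"] = best, _["aligned"] = true,
      _["read_start"] = i,          // 0-based first aligned read base
      _["read_end"] = bi,           // exclusive
      _["ref_start"] = j,           // 0-based within window
      _["ref_end"] = bj,            // exclusive
      _["ops"] = kv, _["lens"] = wrap(lens),
      _["n_mismatch"] = mm, _["n_conversion"] = conv, _["n_indel"] = indel);
}
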
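// Gapped code-word space enumeration and sequence featurization.
//
// Patterns are words over {a,c,g,n,t} with concrete bases at both ends
// ('n' is the gap / wildcard). Digits encode the alphabet in its
// lexicographic order a<c<g<n<t (a=0, c=1, g=2, n=3, t=4), so integer
// order on base-5 codes equals label order.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const char BASES[5] = {'a', 'c', 'g', 'n', 't'};
// complement: a<->t, c<->g, n<->n
static const int COMP[5] = {4, 2, 1, 3, 0};

static long ipow5(int k) {
  long p = 1;
  for (int j = 0; j < k; ++j) p *= 5;
  return p;
}

// Enumerate all canonical code words for k in [k_min, k_max].
// Returns labels (ordered by length then label), one raw-code -> column
// lookup table per k (0-based columns, -1 for codes that are not valid
// patterns), and per-length counts.
// [[Rcpp::export]]
List cw_enumerate_cpp(int k_min, int k_max) {
  std::vector<std::string> labels;
  List lookups(k_max - k_min + 1);
  IntegerVector per_k(k_max - k_min + 1);
  int col = 0;
  for (int k = k_min; k <= k_max; ++k) {
    long pk = ipow5(k);
    IntegerVector lut((R_xlen_t)pk, -1);
    std::vector<int> d(k), e(k);
    int before = col;
    for (long v = 0; v < pk; ++v) {
      long r = v;
      for (int j = k - 1; j >= 0; --j) { d[j] = (int)(r % 5); r /= 5; }
      if (d[0] == 3 || d[k - 1] == 3) continue;  // ends must be concrete
      long rcv = 0;
      for (int j = 0; j < k; ++j) rcv = rcv * 5 + COMP[d[k - 1 - j]];
      if (v > rcv) continue;  // non-canonical orientation, column set earlier
      long r2 = rcv;
      for (int j = k - 1; j >= 0; --j) { e[j] = (int)(r2 % 5); r2 /= 5; }
      std::string lab(2 * k + 1, '|');
      for (int j = 0; j < k; ++j) {
        lab[j] = BASES[d[j]];
        lab[k + 1 + j] = BASES[e[j]];
      }
      labels.push_back(lab);
      lut[v] = col;
      if (rcv != v) lut[rcv] = col;
      ++col;
    }
    per_k[k - k_min] = col - before;
    lookups[k - k_min] = lut;
  }
  return List::create(_["labels"] = wrap(labels),
                      _["lookups"] = lookups,
                      _["per_k"] = per_k,
                      _["m"] = col);
}

// Featurize sequences against an enumerated space. A window matches a
// gapped pattern when every non-gap position is equal; each window
// contributes one match per gappification (2^(k-2) per window), credited
// to the canonical column. Windows containing characters outside
// {a,c,g,t} contribute nothing. Returns COO triplets (0-based).
// [[Rcpp::export]]
List cw_featurize_cpp(CharacterVector seqs, int k_min, int k_max,
                      List lookups, int m_total, bool binary) {
  int nk = k_max - k_min + 1;
  // per-k gap masks: list of gap-position vectors (positions 1..k-2)
  std::vector<std::vector<std::vector<int> > > masks(nk);
  std::vector<std::vector<long> > pows(nk);
  for (int ki = 0; ki < nk; ++ki) {
    int k = k_min + ki;
    pows[ki].resize(k);
    pows[ki][k - 1] = 1;
    for (int j = k - 2; j >= 0; --j) pows[ki][j] = pows[ki][j + 1] * 5;
    int ic = k > 2 ? k - 2 : 0;
    int nmask = 1 << ic;
    masks[ki].resize(nmask);
    for (int msk = 0; msk < nmask; ++msk)
      for (int b = 0; b < ic; ++b)
        if (msk & (1 << b)) masks[ki][msk].push_back(b + 1);
  }
  std::vector<const int*> luts(nk);
  for (int ki = 0; ki < nk; ++ki)
    luts[ki] = INTEGER((SEXP)lookups[ki]);

  std::vector<int> ri, ci;
  std::vector<double> xv;
  std::vector<double> acc((size_t)m_total, 0.0);
  std::vector<int> touched;
  touched.reserve(1 << 16);

  int n = seqs.size();
  std::vector<int> dig;
  for (int si = 0; si < n; ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int L = (int)LENGTH(STRING_ELT(seqs, si));
    dig.assign(L, -1);
    for (int p = 0; p < L; ++p) {
      switch (s[p]) {
        case 'a': case 'A': dig[p] = 0; break;
        case 'c': case 'C': dig[p] = 1; break;
        case 'g': case 'G': dig[p] = 2; break;
        case 't': case 'T': dig[p] = 4; break;
        default: dig[p] = -1;
      }
    }
    touched.clear();
    for (int ki = 0; ki < nk; ++ki) {
      int k = k_min + ki;
      if (L < k) continue;
      long pk5 = pows[ki][0] * 5;  // 5^k
      const int* lut = luts[ki];
      const std::vector<std::vector<int> >& mk = masks[ki];
      int nmask = (int)mk.size();
      long code = 0;
      int run = 0;
      for (int e = 0; e < L; ++e) {
        if (dig[e] < 0) { run = 0; code = 0; continue; }
        ++run;
        code = (code * 5 + dig[e]) % pk5;
        if (run < k) continue;
        int start = e - k + 1;
        for (int msk = 0; msk < nmask; ++msk) {
          long cm = code;
          const std::vector<int>& gaps = mk[msk];
          for (size_t gi = 0; gi < gaps.size(); ++gi) {
            int j = gaps[gi];
            cm += (long)(3 - dig[start + j]) * pows[ki][j];
          }
          int cidx = lut[cm];
          if (acc[cidx] == 0.0) touched.push_back(cidx);
          acc[cidx] += 1.0;
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      int cidx = touched[t];
      ri.push_back(si);
      ci.push_back(cidx);
      xv.push_back(binary ? 1.0 : acc[cidx]);
      acc[cidx] = 0.0;
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xv));
}
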
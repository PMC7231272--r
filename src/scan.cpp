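#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Window scoring over a concatenated promoter sequence.
//
// `seq` holds base codes 0..3 (A,C,G,T) with -1 for any other letter (N and
// the spacer bases separating promoters in the concatenation).  Windows that
// contain a -1 anywhere are skipped, so spacers of length >= L-1 make the
// concatenation behave exactly like per-promoter scanning.
//
// The minus strand is scored with the reverse-complemented score matrix on
// the forward sequence, which is equivalent to scanning the reverse
// complement; the reported offset is the leftmost forward-strand base of the
// window in both cases.

struct HitRec {
  double score;
  int pos;      // 0-based offset in the concatenated sequence
  int strand;   // 0 = '+', 1 = '-'
  bool operator>(const HitRec& o) const {
    if (score != o.score) return score > o.score;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
};

static inline void fill_rc(const NumericMatrix& S, std::vector<double>& rc) {
  const int L = S.nrow();
  rc.resize(4 * L);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < 4; ++b)
      rc[4 * i + b] = S(L - 1 - i, 3 - b);
}

// [[Rcpp::export]]
List cpp_scan(IntegerVector seq, NumericMatrix scoremat,
              IntegerVector starts, IntegerVector lens,
              double threshold, int topk) {
  const int L = scoremat.nrow();
  const int n_prom = starts.size();
  const int* s = INTEGER(seq);

  std::vector<double> fwd(4 * L), rev(4 * L);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < 4; ++b)
      fwd[4 * i + b] = scoremat(i, b);
  fill_rc(scoremat, rev);

  NumericVector pmax(n_prom, R_NegInf);
  std::vector<HitRec> hits;
  // min-heap on score keeps the topk best windows
  std::priority_queue<HitRec, std::vector<HitRec>, std::greater<HitRec> > heap;
  long long n_windows = 0;

  for (int p = 0; p < n_prom; ++p) {
    const int p0 = starts[p];
    const int plen = lens[p];
    if (plen < L) continue;
    const int last = p0 + plen - L;
    double pm = R_NegInf;
    for (int j = p0; j <= last; ++j) {
      double sf = 0.0, sr = 0.0;
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        const int b = s[j + i];
        if (b < 0) { ok = false; break; }
        sf += fwd[4 * i + b];
        sr += rev[4 * i + b];
      }
      if (!ok) continue;
      n_windows += 2;
      if (sf > pm) pm = sf;
      if (sr > pm) pm = sr;
      if (topk > 0) {
        HitRec hf = {sf, j, 0};
        if ((int)heap.size() < topk) heap.push(hf);
        else if (hf > heap.top()) { heap.pop(); heap.push(hf); }
        HitRec hr = {sr, j, 1};
        if ((int)heap.size() < topk) heap.push(hr);
        else if (hr > heap.top()) { heap.pop(); heap.push(hr); }
      } else {
        if (sf >= threshold) { HitRec h = {sf, j, 0}; hits.push_back(h); }
        if (sr >= threshold) { HitRec h = {sr, j, 1}; hits.push_back(h); }
      }
    }
    pmax[p] = pm;
  }

  if (topk > 0) {
    hits.clear();
    while (!heap.empty()) { hits.push_back(heap.top()); heap.pop(); }
    std::reverse(hits.begin(), hits.end());  // best first
  }

  const int nh = hits.size();
  NumericVector h_score(nh);
  IntegerVector h_pos(nh), h_strand(nh);
  for (int i = 0; i < nh; ++i) {
    h_score[i] = hits[i].score;
    h_pos[i] = hits[i].pos;
    h_strand[i] = hits[i].strand;
  }

  return List::create(_["pmax"] = pmax,
                      _["pos"] = h_pos,
                      _["strand"] = h_strand,
                      _["score"] = h_score,
                      _["n_windows"] = (double)n_windows);
}
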
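// Ruzzo-Tompa decomposition of a score vector into all maximal-scoring
// (positive) subsequences.  Linear-time stack algorithm; returned segments
// are disjoint and reported here in left-to-right coordinate order.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {
struct Cand {
  int start, end;   // 0-based half-open column indices
  double L, R;      // cumulative score before start / at end
};
}

//' @noRd
// [[Rcpp::export(name = ".ruzzo_tompa_cpp")]]
DataFrame ruzzo_tompa_cpp(NumericVector scores) {
  std::vector<Cand> st;
  double cum = 0.0;
  const int m = scores.size();
  for (int i = 0; i < m; ++i) {
    const double x = scores[i];
    cum += x;
    if (!(x > 0)) continue;
    Cand k{i, i + 1, cum - x, cum};
    for (;;) {
      // rightmost candidate j with L_j < L_k
      int j = (int)st.size() - 1;
      while (j >= 0 && st[j].L >= k.L) --j;
      if (j < 0 || st[j].R >= k.R) {
        st.push_back(k);
        break;
      }
      // merge: extend candidate j through k, drop everything between
      st[j].end = k.end;
      st[j].R = k.R;
      k = st[j];
      st.resize(j);
    }
  }
  const int ns = (int)st.size();
  IntegerVector start(ns), end(ns);
  NumericVector score(ns);
  for (int i = 0; i < ns; ++i) {
    start[i] = st[i].start;
    end[i] = st[i].end;
    score[i] = st[i].R - st[i].L;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["score"] = score);
}
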
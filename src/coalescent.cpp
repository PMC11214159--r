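// Neutral infinite-sites coalescent with crossover recombination.
//
// Exact ancestral-recombination-graph construction in the style of Hudson's
// ms: each lineage carries a list of genomic segments (on [0,1)) that are
// ancestral to the sample, tagged with the set of sampled haplotypes
// descending from the lineage over that segment.  Coalescence merges segment
// lists (union of descendant sets); spans whose descendant set reaches the
// full sample have found their MRCA and are dropped, so every mutation that
// is recorded is segregating (0 < derived count < n) by construction.
// Recombination splits a lineage at a uniform breakpoint within the extent
// of its ancestral material (trapped non-ancestral material recombines too).
// Mutations are laid down interval by interval with rate (theta/2) per unit
// of ancestral branch length, positions uniform -- the infinite-sites model.
//
// Time is in units of 2N generations; theta = 4N*mu and rho = 4N*r are the
// locus-wide population-scaled rates.  Uses R's RNG so set.seed() in R
// controls everything.  Per-lineage span (recombination target length) and
// ancestral length (mutation target length) are kept incrementally so each
// event costs O(k) at worst, not O(total segments).

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;      // half-open [l, r) on [0,1)
  uint64_t d;       // bitmask of descendant sample haplotypes
};

struct Lineage {
  std::vector<Seg> segs;
  double span;      // rightmost - leftmost ancestral endpoint
  double anc;       // total ancestral length

  void refresh() {
    if (segs.empty()) { span = anc = 0.0; return; }
    span = segs.back().r - segs.front().l;
    anc = 0.0;
    for (const Seg &g : segs) anc += g.r - g.l;
  }
};

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { c += (int)(x & 1); x >>= 1; }
  return c;
#endif
}

// merge two segment lists; pieces whose descendant set is `full` are
// dropped (MRCA reached over that span)
void merge_lineages(const Lineage &a, const Lineage &b, uint64_t full,
                    Lineage &out) {
  out.segs.clear();
  size_t ia = 0, ib = 0;
  const std::vector<Seg> &A = a.segs, &B = b.segs;
  double pos;
  {
    double la = A.empty() ? 1.0 : A.front().l;
    double lb = B.empty() ? 1.0 : B.front().l;
    pos = std::min(la, lb);
  }
  while (ia < A.size() || ib < B.size()) {
    while (ia < A.size() && A[ia].r <= pos) ++ia;
    while (ib < B.size() && B[ib].r <= pos) ++ib;
    if (ia >= A.size() && ib >= B.size()) break;

    bool ina = ia < A.size() && A[ia].l <= pos && pos < A[ia].r;
    bool inb = ib < B.size() && B[ib].l <= pos && pos < B[ib].r;

    if (!ina && !inb) {
      double nxt = 1.0;
      if (ia < A.size()) nxt = std::min(nxt, A[ia].l);
      if (ib < B.size()) nxt = std::min(nxt, B[ib].l);
      pos = nxt;
      continue;
    }
    double nxt = 1.0;
    if (ia < A.size()) nxt = std::min(nxt, ina ? A[ia].r : A[ia].l);
    if (ib < B.size()) nxt = std::min(nxt, inb ? B[ib].r : B[ib].l);

    uint64_t d = (ina ? A[ia].d : 0ULL) | (inb ? B[ib].d : 0ULL);
    if (d != full && nxt > pos) {
      if (!out.segs.empty() && out.segs.back().r == pos &&
          out.segs.back().d == d)
        out.segs.back().r = nxt;      // compact equal-mask neighbours
      else
        out.segs.push_back(Seg{pos, nxt, d});
    }
    pos = nxt;
  }
  out.refresh();
}

}  // namespace

//' @name sim_arg_cpp
//' @title Low-level ARG simulator (internal)
//' @noRd
// [[Rcpp::export(name = ".sim_arg_cpp")]]
List sim_arg_cpp(int n, double theta, double rho, int reps,
                 bool detail = false) {
  if (n < 2 || n > 64) stop("sample size n must be in [2, 64]");
  if (theta < 0 || rho < 0) stop("theta and rho must be non-negative");
  if (reps < 1) stop("reps must be >= 1");

  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);

  List res(reps);

  std::vector<Lineage> lin;
  std::vector<double> mpos;
  std::vector<uint64_t> mmask;
  Lineage merged;

  for (int rep = 0; rep < reps; ++rep) {
    lin.clear();
    for (int i = 0; i < n; ++i) {
      Lineage x;
      x.segs.push_back(Seg{0.0, 1.0, 1ULL << i});
      x.refresh();
      lin.push_back(std::move(x));
    }
    mpos.clear();
    mmask.clear();

    double tot_span = (double)n;   // sum of per-lineage spans
    double tot_anc = (double)n;    // sum of per-lineage ancestral lengths
    long iter = 0;

    while (lin.size() >= 2) {
      const size_t k = lin.size();
      if (((++iter) & 0xFFF) == 0) {
        // resync incrementally-tracked totals against drift
        tot_span = tot_anc = 0.0;
        for (const Lineage &x : lin) { tot_span += x.span; tot_anc += x.anc; }
        Rcpp::checkUserInterrupt();
      }
      const double r_rate = 0.5 * rho * tot_span;
      const double c_rate = 0.5 * (double)k * (double)(k - 1);
      const double total = r_rate + c_rate;

      const double dt = R::exp_rand() / total;

      if (theta > 0 && tot_anc > 0) {
        const int nm = (int)R::rpois(dt * 0.5 * theta * tot_anc);
        for (int m = 0; m < nm; ++m) {
          double u = R::unif_rand() * tot_anc;
          bool placed = false;
          for (const Lineage &x : lin) {
            if (u >= x.anc) { u -= x.anc; continue; }
            for (const Seg &g : x.segs) {
              const double len = g.r - g.l;
              if (u < len) {
                mpos.push_back(g.l + u);
                mmask.push_back(g.d);
                placed = true;
                break;
              }
              u -= len;
            }
            break;
          }
          (void)placed;
        }
      }

      if (R::unif_rand() * total < c_rate) {
        // coalescence of a uniform random pair
        size_t i = (size_t)(R::unif_rand() * k);
        size_t j = (size_t)(R::unif_rand() * (k - 1));
        if (i >= k) i = k - 1;
        if (j >= i) ++j;
        tot_span -= lin[i].span + lin[j].span;
        tot_anc -= lin[i].anc + lin[j].anc;
        merge_lineages(lin[i], lin[j], full, merged);
        if (i < j) std::swap(i, j);   // drop larger index first (swap-remove)
        lin[i] = std::move(lin.back()); lin.pop_back();
        lin[j] = std::move(lin.back()); lin.pop_back();
        if (!merged.segs.empty()) {
          tot_span += merged.span;
          tot_anc += merged.anc;
          lin.push_back(merged);
        }
      } else {
        // recombination: lineage chosen proportional to its extent
        double u = R::unif_rand() * tot_span;
        size_t i = 0;
        for (; i + 1 < k; ++i) {
          if (u < lin[i].span) break;
          u -= lin[i].span;
        }
        Lineage &x = lin[i];
        if (x.segs.empty()) continue;
        const double bp = x.segs.front().l + R::unif_rand() * x.span;
        Lineage left, right;
        for (const Seg &g : x.segs) {
          if (g.r <= bp) left.segs.push_back(g);
          else if (g.l >= bp) right.segs.push_back(g);
          else {
            left.segs.push_back(Seg{g.l, bp, g.d});
            right.segs.push_back(Seg{bp, g.r, g.d});
          }
        }
        if (left.segs.empty() || right.segs.empty()) continue;
        left.refresh();
        right.refresh();
        tot_span += left.span + right.span - x.span;
        tot_anc += left.anc + right.anc - x.anc;
        lin[i] = std::move(left);
        lin.push_back(std::move(right));
      }
    }

    const int S = (int)mpos.size();
    IntegerVector cnt(S);
    NumericVector pos(S);
    for (int s = 0; s < S; ++s) {
      pos[s] = mpos[s];
      cnt[s] = popcount64(mmask[s]);
    }
    if (detail) {
      LogicalMatrix car(S, n);
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < n; ++i)
          car(s, i) = (mmask[s] >> i) & 1ULL;
      res[rep] = List::create(_["pos"] = pos, _["count"] = cnt,
                              _["carriers"] = car);
    } else {
      res[rep] = List::create(_["pos"] = pos, _["count"] = cnt);
    }
  }
  return res;
}
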
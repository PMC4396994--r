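// Two-population structured coalescent with recombination and an
// instantaneous migration pulse (backward-in-time view of a burst of
// introgression from population 2 into population 1).
//
// Time contract: public divergence/pulse times arrive already divided by 4
// (internal unit = 4N generations). Any pair of lineages within a
// population coalesces at rate 2 per internal unit, so the expected
// within-population pairwise coalescence time is 0.5 units = 2N
// generations. Mutations fall at rate theta per unit branch length per
// unit of ancestral span, giving E[pi] = theta and E[S] = theta * H_{n-1}
// for a panmictic sample of n.
//
// Uses R's RNG throughout so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;      // half-open [l, r) on [0, 1)
  uint64_t d;       // bitmask of descendant samples
};

struct Lin {
  std::vector<Seg> segs;  // sorted, disjoint, non-empty
  int pop;                // 1 or 2; ignored once populations merge
  double birth;           // time the lineage came into existence
};

inline double seg_total_len(const std::vector<Seg>& s) {
  double L = 0.0;
  for (const Seg& g : s) L += g.r - g.l;
  return L;
}

inline double seg_span(const std::vector<Seg>& s) {
  return s.back().r - s.front().l;
}

// Merge the ancestral material of two coalescing lineages (both segment
// lists sorted and disjoint). Intervals whose descendant set becomes the
// full sample have found their MRCA and are dropped from further
// tracking. Linear two-pointer sweep over the interval boundaries.
void merge_segs(const std::vector<Seg>& A, const std::vector<Seg>& B,
                uint64_t full, std::vector<Seg>& out) {
  out.clear();
  size_t ia = 0, ib = 0;
  double cur = -1.0;
  auto emit = [&](double l, double r, uint64_t m) {
    if (m == 0 || m == full || r <= l) return;
    if (!out.empty() && out.back().r == l && out.back().d == m)
      out.back().r = r;
    else
      out.push_back({l, r, m});
  };
  while (ia < A.size() || ib < B.size()) {
    // next boundary after cur
    double lo;
    if (ia < A.size() && ib < B.size())
      lo = std::min(std::max(cur, A[ia].l), std::max(cur, B[ib].l));
    else if (ia < A.size())
      lo = std::max(cur, A[ia].l);
    else
      lo = std::max(cur, B[ib].l);

    // elementary interval [lo, hi): bounded by the nearest endpoint
    double hi = R_PosInf;
    uint64_t m = 0;
    if (ia < A.size()) {
      if (A[ia].l > lo) hi = std::min(hi, A[ia].l);
      else { m |= A[ia].d; hi = std::min(hi, A[ia].r); }
    }
    if (ib < B.size()) {
      if (B[ib].l > lo) hi = std::min(hi, B[ib].l);
      else { m |= B[ib].d; hi = std::min(hi, B[ib].r); }
    }
    emit(lo, hi, m);
    cur = hi;
    while (ia < A.size() && A[ia].r <= cur) ++ia;
    while (ib < B.size() && B[ib].r <= cur) ++ib;
  }
}

struct Mut {
  double pos;
  uint64_t d;
};

// Poisson mutations over the lineage's lifetime; the segment structure is
// constant between the events that create and destroy a lineage, so each
// mutation inherits the descendant set of the segment it lands on.
void emit_mutations(const Lin& lin, double t_death, double theta,
                    std::vector<Mut>& muts) {
  const double L = seg_total_len(lin.segs);
  const double dt = t_death - lin.birth;
  if (L <= 0.0 || dt <= 0.0 || theta <= 0.0) return;
  const int m = (int) R::rpois(theta * L * dt);
  for (int j = 0; j < m; ++j) {
    double u = unif_rand() * L;
    for (const Seg& s : lin.segs) {
      const double len = s.r - s.l;
      if (u < len) { muts.push_back({s.l + u, s.d}); break; }
      u -= len;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_window_cpp")]]
List sim_window_cpp(double theta, double rho, double tau_d4, double tau_m4,
                    double lam, int n1, int n2, double max_events) {
  const int n = n1 + n2;
  if (n < 2 || n > 64) stop("total sample size must be in [2, 64]");
  const uint64_t full = (n == 64) ? ~UINT64_C(0)
                                  : ((UINT64_C(1) << n) - 1);

  std::vector<Lin> lins;
  lins.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    Lin l;
    l.segs.push_back({0.0, 1.0, UINT64_C(1) << i});
    l.pop = (i < n1) ? 1 : 2;
    l.birth = 0.0;
    lins.push_back(std::move(l));
  }

  std::vector<Mut> muts;
  double t = 0.0;
  bool merged = (tau_d4 <= 0.0);
  // A pulse exactly at the divergence time is a no-op (the populations
  // are one deme from then on), so it is only scheduled for tau_m < tau_d.
  bool pulse_pending = (lam > 0.0 && tau_m4 < tau_d4);
  bool migrant = false;
  double n_events = 0.0;

  // incrementally maintained totals (k1 holds the single-deme count once
  // the populations have merged)
  int k1 = merged ? n : n1, k2 = merged ? 0 : n2;
  double span_sum = (double) n;  // every sample starts with span 1

  std::vector<Seg> scratch;  // reused merge buffer

  auto drop_lineage = [&](size_t i) {  // swap-and-pop
    span_sum -= seg_span(lins[i].segs);
    if (!merged) { if (lins[i].pop == 1) --k1; else --k2; }
    else --k1;
    lins[i] = std::move(lins.back());
    lins.pop_back();
  };
  auto add_lineage = [&](Lin&& l) {
    span_sum += seg_span(l.segs);
    if (!merged) { if (l.pop == 1) ++k1; else ++k2; }
    else ++k1;
    lins.push_back(std::move(l));
  };

  while (!lins.empty()) {
    const double rc1 = merged ? (double) k1 * (k1 - 1)
                              : (double) k1 * (k1 - 1);
    const double rc2 = merged ? 0.0 : (double) k2 * (k2 - 1);
    const double rr = rho * span_sum;
    const double total = rc1 + rc2 + rr;

    double tb = R_PosInf;
    if (pulse_pending) tb = tau_m4;
    if (!merged && tau_d4 < tb) tb = tau_d4;

    bool at_boundary;
    if (total <= 0.0) {
      if (!R_finite(tb)) stop("coalescent stalled: no events possible");
      t = tb;
      at_boundary = true;
    } else {
      const double dt = exp_rand() / total;
      if (t + dt >= tb) { t = tb; at_boundary = true; }
      else { t += dt; at_boundary = false; }
    }

    if (at_boundary) {
      if (pulse_pending) {
        // migration pulse: each lineage residing in population 1 moves
        // to population 2 independently with probability lam (binomial
        // over the k resident lineages, expectation k*lam)
        for (Lin& l : lins) {
          if (l.pop == 1 && unif_rand() < lam) {
            l.pop = 2; --k1; ++k2;
            migrant = true;  // all live lineages carry ancestral material
          }
        }
        pulse_pending = false;
      } else {
        merged = true;
        k1 += k2; k2 = 0;  // one deme from here on
      }
      continue;
    }

    if (++n_events > max_events)
      stop("event ceiling exceeded (runaway ancestral recombination graph)");

    const double u = unif_rand() * total;
    if (u < rc1 + rc2) {
      // coalescence: choose the deme, then an unordered pair within it
      const int pop = merged ? 0 : (u < rc1 ? 1 : 2);
      const int k = merged ? k1 : (pop == 1 ? k1 : k2);
      // draw two distinct ranks among the deme's k lineages
      int a = (int) (unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int) (unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      // map ranks to indices
      int ia = -1, ib = -1, rank = 0;
      for (size_t i = 0; i < lins.size(); ++i) {
        if (!merged && lins[i].pop != pop) continue;
        if (rank == a) ia = (int) i;
        if (rank == b) ib = (int) i;
        ++rank;
      }
      emit_mutations(lins[ia], t, theta, muts);
      emit_mutations(lins[ib], t, theta, muts);

      Lin child;
      child.pop = lins[ia].pop;
      child.birth = t;
      merge_segs(lins[ia].segs, lins[ib].segs, full, scratch);
      child.segs.swap(scratch);

      drop_lineage((size_t) std::max(ia, ib));
      drop_lineage((size_t) std::min(ia, ib));
      if (!child.segs.empty()) add_lineage(std::move(child));
    } else {
      // recombination: pick a lineage proportional to its ancestral
      // span, split at a uniform breakpoint within that span
      double v = (u - rc1 - rc2) / rho;
      int pick = -1;
      for (size_t i = 0; i < lins.size(); ++i) {
        const double sp = seg_span(lins[i].segs);
        if (v < sp) { pick = (int) i; break; }
        v -= sp;
      }
      if (pick < 0) pick = (int) lins.size() - 1;
      Lin& l = lins[pick];
      const double lo = l.segs.front().l, hi = l.segs.back().r;
      const double bp = lo + unif_rand() * (hi - lo);

      emit_mutations(l, t, theta, muts);

      Lin left, right;
      left.pop = right.pop = l.pop;
      left.birth = right.birth = t;
      for (const Seg& s : l.segs) {
        if (s.r <= bp) left.segs.push_back(s);
        else if (s.l >= bp) right.segs.push_back(s);
        else {
          left.segs.push_back({s.l, bp, s.d});
          right.segs.push_back({bp, s.r, s.d});
        }
      }
      drop_lineage((size_t) pick);
      if (!left.segs.empty()) add_lineage(std::move(left));
      if (!right.segs.empty()) add_lineage(std::move(right));
    }
  }

  // infinite-sites output: biallelic 0/1 columns in positional order,
  // ancestral state 0
  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  const int S = (int) muts.size();
  IntegerMatrix mat(n, S);
  NumericVector pos(S);
  for (int j = 0; j < S; ++j) {
    pos[j] = muts[j].pos;
    for (int i = 0; i < n; ++i)
      if (muts[j].d & (UINT64_C(1) << i)) mat(i, j) = 1;
  }

  return List::create(_["mat"] = mat, _["positions"] = pos,
                      _["migrant"] = migrant, _["n_events"] = n_events);
}

// Pairwise Hamming machinery shared by the window statistics: counts of
// differing sites and of mutually non-missing sites for every pair of
// rows. Missing states are NA.
// [[Rcpp::export(name = ".hamming_counts_cpp")]]
List hamming_counts_cpp(IntegerMatrix x) {
  const int n = x.nrow(), S = x.ncol();
  IntegerMatrix diff(n, n), comp(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int d = 0, c = 0;
      for (int j = 0; j < S; ++j) {
        const int xa = x(a, j), xb = x(b, j);
        if (xa == NA_INTEGER || xb == NA_INTEGER) continue;
        ++c;
        if (xa != xb) ++d;
      }
      diff(a, b) = diff(b, a) = d;
      comp(a, b) = comp(b, a) = c;
    }
  }
  return List::create(_["diff"] = diff, _["comparable"] = comp);
}
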
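// Greedy earliest disjoint occurrence counting for ordered multi-cell event
// sequences, plus the circular-shift permutation null. Constraints: each
// consecutive step of an occurrence must satisfy gap < dt <= lag (strict
// lower bound avoids counting near-simultaneous bursts as sequences).
// Occurrences consume their events; anchors are scanned in time order and
// each level picks the earliest unused feasible event, backtracking within a
// chain when a deeper level cannot be completed.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

typedef std::vector<std::vector<double> > TrainSet;

static bool build_chain(const TrainSet& tt,
                        std::vector<std::vector<char> >& used,
                        int level, double prev_time,
                        double gap, double lag,
                        std::vector<int>& picks) {
  const int m = (int) tt.size();
  if (level == m) return true;
  const std::vector<double>& ev = tt[level];
  // earliest event strictly greater than prev_time + gap
  int i = (int) (std::upper_bound(ev.begin(), ev.end(), prev_time + gap) - ev.begin());
  for (; i < (int) ev.size(); ++i) {
    if (ev[i] > prev_time + lag) break;
    if (used[level][i]) continue;
    picks[level] = i;
    if (build_chain(tt, used, level + 1, ev[i], gap, lag, picks)) return true;
  }
  return false;
}

static int count_greedy(const TrainSet& tt, double gap, double lag,
                        std::vector<std::vector<int> >* occ = NULL) {
  const int m = (int) tt.size();
  std::vector<std::vector<char> > used(m);
  for (int c = 0; c < m; ++c) used[c].assign(tt[c].size(), 0);
  int count = 0;
  std::vector<int> picks(m);
  for (int a = 0; a < (int) tt[0].size(); ++a) {
    if (used[0][a]) continue;
    picks[0] = a;
    if (build_chain(tt, used, 1, tt[0][a], gap, lag, picks)) {
      for (int c = 0; c < m; ++c) used[c][picks[c]] = 1;
      ++count;
      if (occ) occ->push_back(picks);
    }
  }
  return count;
}

static TrainSet as_trainset(const List& times) {
  TrainSet tt(times.size());
  for (int c = 0; c < times.size(); ++c) {
    NumericVector v = times[c];
    tt[c] = std::vector<double>(v.begin(), v.end());
  }
  return tt;
}

// [[Rcpp::export]]
int count_motif_cpp(List times, double gap, double lag) {
  TrainSet tt = as_trainset(times);
  return count_greedy(tt, gap, lag);
}

// [[Rcpp::export]]
NumericMatrix motif_occurrences_cpp(List times, double gap, double lag) {
  TrainSet tt = as_trainset(times);
  std::vector<std::vector<int> > occ;
  count_greedy(tt, gap, lag, &occ);
  const int m = (int) tt.size();
  NumericMatrix out((int) occ.size(), m);
  for (int k = 0; k < (int) occ.size(); ++k)
    for (int c = 0; c < m; ++c) out(k, c) = tt[c][occ[k][c]];
  return out;
}

// Circular-shift null: every cell except the anchor is shifted by its own
// offset modulo the segment length (times are relative to segment start),
// re-sorted, and the motif recounted with the same greedy counter. Row k of
// `offsets` holds the per-replicate offsets for cells 2..m.
// [[Rcpp::export]]
IntegerVector null_counts_cpp(List times, double gap, double lag,
                              double duration, NumericMatrix offsets) {
  TrainSet base = as_trainset(times);
  const int m = (int) base.size();
  if (offsets.ncol() != m - 1) stop("offsets must have one column per non-anchor cell");
  const int K = offsets.nrow();
  IntegerVector out(K);
  TrainSet shifted(m);
  for (int k = 0; k < K; ++k) {
    shifted[0] = base[0];
    for (int c = 1; c < m; ++c) {
      std::vector<double> v = base[c];
      const double off = offsets(k, c - 1);
      for (size_t i = 0; i < v.size(); ++i) {
        double t = v[i] + off;
        t -= duration * std::floor(t / duration);  // wrap into [0, duration)
        v[i] = t;
      }
      std::sort(v.begin(), v.end());
      shifted[c] = v;
    }
    out[k] = count_greedy(shifted, gap, lag);
  }
  return out;
}

// Counts for many ordered pairs in one call (enumeration hot path).
// `pair_idx` is a 2-column 1-based index matrix into `times`.
// [[Rcpp::export]]
IntegerVector pair_counts_cpp(List times, IntegerMatrix pair_idx,
                              double gap, double lag) {
  TrainSet all = as_trainset(times);
  IntegerVector out(pair_idx.nrow());
  TrainSet tt(2);
  for (int p = 0; p < pair_idx.nrow(); ++p) {
    tt[0] = all[pair_idx(p, 0) - 1];
    tt[1] = all[pair_idx(p, 1) - 1];
    out[p] = count_greedy(tt, gap, lag);
  }
  return out;
}
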
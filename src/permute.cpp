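#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Chained focal data-stream permutation of proximity events.
//
// Events are (dyad, slot) pairs carrying a block id (date x group stratum;
// 0 = frozen cross-group event, never touched). An elementary swap picks
// two events of the same block with four distinct individuals, say i-j at
// t1 and k-l at t2, and rewires them to (i-l, t1) and (k-j, t2) (or the
// mirror orientation), rejecting proposals that would duplicate an
// existing (dyad, slot) event. Each emitted sample is separated from the
// previous one by `swaps_per_step` proposals; the chain starts with
// `burn_in` proposals. Per-individual event counts within each block, the
// total event count and the slot multiset are invariant.
//
// Uses R's RNG so results are reproducible under set.seed().

static inline long long key_of(int a, int b, int slot, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return ((long long)(lo * n + hi)) * 2000000LL + slot;
}

// [[Rcpp::export(name = ".permute_chain")]]
List permute_chain(IntegerVector a, IntegerVector b, IntegerVector slot,
                   IntegerVector block, int n_nodes, int n_perm,
                   int swaps_per_step, int burn_in) {
  int m = a.size();
  std::vector<int> ca(a.begin(), a.end()), cb(b.begin(), b.end());

  // block -> event indices
  int n_block = 0;
  for (int e = 0; e < m; ++e) if (block[e] > n_block) n_block = block[e];
  std::vector<std::vector<int>> members(n_block + 1);
  std::vector<int> swappable;
  for (int e = 0; e < m; ++e)
    if (block[e] > 0) members[block[e]].push_back(e);
  for (int e = 0; e < m; ++e)
    if (block[e] > 0 && members[block[e]].size() >= 2) swappable.push_back(e);

  std::unordered_set<long long> seen;
  seen.reserve(m * 2);
  for (int e = 0; e < m; ++e) seen.insert(key_of(ca[e], cb[e], slot[e], n_nodes));
  if ((int)seen.size() != m)
    stop("duplicate (dyad, slot) events in the input stream");

  RNGScope scope;
  List out(n_perm);
  long long accepted = 0, proposed = 0;

  auto do_swaps = [&](int n_swaps) {
    if (swappable.empty()) return;
    for (int s = 0; s < n_swaps; ++s) {
      ++proposed;
      int e1 = swappable[(int)(unif_rand() * swappable.size())];
      const std::vector<int>& blk = members[block[e1]];
      int e2 = blk[(int)(unif_rand() * blk.size())];
      if (e1 == e2) continue;
      int i = ca[e1], j = cb[e1], k = ca[e2], l = cb[e2];
      if (i == k || i == l || j == k || j == l) continue;
      // two legal rewirings preserve everyone's event count; pick one
      int a1, b1, a2, b2;
      if (unif_rand() < 0.5) { a1 = i; b1 = l; a2 = k; b2 = j; }
      else                   { a1 = i; b1 = k; a2 = j; b2 = l; }
      long long k_old1 = key_of(ca[e1], cb[e1], slot[e1], n_nodes);
      long long k_old2 = key_of(ca[e2], cb[e2], slot[e2], n_nodes);
      long long k_new1 = key_of(a1, b1, slot[e1], n_nodes);
      long long k_new2 = key_of(a2, b2, slot[e2], n_nodes);
      if (k_new1 == k_new2) continue;
      if (seen.count(k_new1) || seen.count(k_new2)) continue;
      seen.erase(k_old1); seen.erase(k_old2);
      seen.insert(k_new1); seen.insert(k_new2);
      ca[e1] = a1 < b1 ? a1 : b1; cb[e1] = a1 < b1 ? b1 : a1;
      ca[e2] = a2 < b2 ? a2 : b2; cb[e2] = a2 < b2 ? b2 : a2;
      ++accepted;
    }
  };

  do_swaps(burn_in);
  for (int r = 0; r < n_perm; ++r) {
    do_swaps(swaps_per_step);
    IntegerMatrix samp(m, 2);
    for (int e = 0; e < m; ++e) { samp(e, 0) = ca[e]; samp(e, 1) = cb[e]; }
    out[r] = samp;
  }
  out.attr("accepted") = (double)accepted;
  out.attr("proposed") = (double)proposed;
  return out;
}
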
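// Modified BUILD over rooted splits, plus the greedy ranked-incorporation
// loop. Leaves are 0-based integers; a split is (include, exclude) index
// vectors. The recursion at leaf set C connects include-sets of the active
// splits (|include ∩ C| >= 2 and exclude ∩ C nonempty) in a union-find over
// C; connected components become children. A single component with an
// active split means no tree displays the split set: INCOMPATIBLE.
//
// With triplet inputs this is exactly Aho's BUILD; larger splits behave as
// if decomposed into all implied triplets.

#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

namespace {

struct Split {
  std::vector<int> inc, exc;
};

struct Builder {
  int L;                       // number of leaves
  std::vector<int> parent;     // nodes: 0..L-1 leaves; internals appended
  bool failed;

  explicit Builder(int L_) : L(L_), parent(L_, -2), failed(false) {}

  int new_internal() {
    parent.push_back(-2);
    return (int)parent.size() - 1;
  }

  // C: leaf ids at this level; act: indices into splits of active splits
  int solve(const std::vector<Split>& splits, const std::vector<int>& C,
            const std::vector<int>& act) {
    if (C.size() == 1) return C[0];

    std::vector<int> pos(L, -1);  // leaf -> position in C
    for (size_t i = 0; i < C.size(); ++i) pos[C[i]] = (int)i;

    // union-find over positions in C
    std::vector<int> uf(C.size());
    for (size_t i = 0; i < uf.size(); ++i) uf[i] = (int)i;
    std::function<int(int)> find = [&](int x) {
      while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
      return x;
    };

    std::vector<int> live;  // splits still active at this level
    live.reserve(act.size());
    for (int si : act) {
      const Split& s = splits[si];
      int n_inc = 0, first = -1;
      for (int x : s.inc) if (pos[x] >= 0) { ++n_inc; if (first < 0) first = pos[x]; }
      if (n_inc < 2) continue;
      bool exc_present = false;
      for (int x : s.exc) if (pos[x] >= 0) { exc_present = true; break; }
      if (!exc_present) continue;  // C itself displays this split
      live.push_back(si);
      int r0 = find(first);
      for (int x : s.inc) {
        if (pos[x] < 0) continue;
        int r = find(pos[x]);
        if (r != r0) uf[r] = r0;
      }
    }

    // collect components
    std::vector<int> comp_id(C.size(), -1);
    std::vector<std::vector<int>> comps;
    for (size_t i = 0; i < C.size(); ++i) {
      int r = find((int)i);
      if (comp_id[r] < 0) {
        comp_id[r] = (int)comps.size();
        comps.push_back(std::vector<int>());
      }
      comp_id[i] = comp_id[r];
      comps[comp_id[r]].push_back(C[i]);
    }

    if (comps.size() == 1 && !live.empty()) { failed = true; return -1; }

    int me = new_internal();
    // assign each live split to the component holding its include set
    std::vector<std::vector<int>> comp_act(comps.size());
    for (int si : live) {
      const Split& s = splits[si];
      for (int x : s.inc) {
        if (pos[x] >= 0) { comp_act[comp_id[find(pos[x])]].push_back(si); break; }
      }
    }
    for (size_t c = 0; c < comps.size(); ++c) {
      int child;
      if (comps[c].size() == 1) child = comps[c][0];
      else {
        child = solve(splits, comps[c], comp_act[c]);
        if (failed) return -1;
      }
      parent[child] = me;
    }
    return me;
  }
};

std::vector<Split> convert(const List& includes, const List& excludes) {
  std::vector<Split> splits(includes.size());
  for (int i = 0; i < includes.size(); ++i) {
    IntegerVector inc = includes[i], exc = excludes[i];
    splits[i].inc.assign(inc.begin(), inc.end());
    splits[i].exc.assign(exc.begin(), exc.end());
  }
  return splits;
}

List run_build(const std::vector<Split>& splits, const std::vector<int>& which,
               int L) {
  Builder b(L);
  std::vector<int> C(L);
  for (int i = 0; i < L; ++i) C[i] = i;
  int root = b.solve(splits, C, which);
  if (b.failed) return List::create(Named("success") = false);
  b.parent[root] = -1;
  IntegerVector par(b.parent.size());
  for (size_t i = 0; i < b.parent.size(); ++i) par[i] = b.parent[i] + 1;
  return List::create(Named("success") = true, Named("parent") = par,
                      Named("root") = root + 1);
}

} // namespace

// [[Rcpp::export(name = ".build_compatible_cpp")]]
List build_compatible_cpp(List includes, List excludes, int n_leaves) {
  std::vector<Split> splits = convert(includes, excludes);
  std::vector<int> which(splits.size());
  for (size_t i = 0; i < which.size(); ++i) which[i] = (int)i;
  return run_build(splits, which, n_leaves);
}

// Greedy ranked incorporation: candidate i is accepted iff the accepted set
// plus i is buildable (a full BUILD re-run per candidate, semantics first).
// [[Rcpp::export(name = ".consistent_splits_cpp")]]
List consistent_splits_cpp(List includes, List excludes, int n_leaves) {
  std::vector<Split> splits = convert(includes, excludes);
  std::vector<int> accepted;
  LogicalVector ok(splits.size());
  for (size_t i = 0; i < splits.size(); ++i) {
    std::vector<int> trial = accepted;
    trial.push_back((int)i);
    Builder b(n_leaves);
    std::vector<int> C(n_leaves);
    for (int j = 0; j < n_leaves; ++j) C[j] = j;
    b.solve(splits, C, trial);
    ok[i] = !b.failed;
    if (!b.failed) accepted.push_back((int)i);
  }
  List tree = run_build(splits, accepted, n_leaves);
  return List::create(Named("accepted") = ok, Named("tree") = tree);
}
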
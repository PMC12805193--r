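#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>
#include <numeric>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cardinality-bounded K-coloring feasibility.
//
// Colors the subgraph induced by non-isolated vertices such that adjacent
// vertices receive different colors and color k is used at most caps[k]
// times.  Isolated vertices are left uncolored (they can absorb any leftover
// capacity).  K = 2 is solved exactly in polynomial time: each connected
// component is two-colored by BFS and the orientation of the components is
// chosen by a subset-sum dynamic program over the side counts.  K >= 3 uses
// DSATUR-ordered backtracking with capacity pruning and color-symmetry
// breaking; the search is exact but guarded by a node budget so that a
// blow-up surfaces as a distinct solver-limit error, never as "infeasible".
// ---------------------------------------------------------------------------

namespace {

// General-K solver.  Connected components are colored one after another
// (largest first); between components the only coupling is the vector of
// remaining color capacities, so suffixes proven infeasible are memoized on
// (component index, sorted remaining capacities).  Within a component the
// search is DSATUR-ordered backtracking; candidate colors are tried in
// order of decreasing remaining capacity (load balancing), and colors not
// yet used inside the component with equal remaining capacity are
// interchangeable, so only the first of each such class is branched on.
struct ColorProblem {
  int n, K;
  std::vector<std::vector<int> > adj;
  std::vector<int> caps, color, used, usedInComp;
  std::vector<std::vector<int> > comps;  // vertex lists, largest first
  std::set<std::pair<int, std::vector<int> > > failed;
  double nodes, node_limit;
  bool budget_hit;

  void build_components() {
    std::vector<int> comp(n, -1);
    for (int v0 = 0; v0 < n; ++v0) {
      if (adj[v0].empty() || comp[v0] >= 0) continue;
      std::vector<int> stack(1, v0), mem;
      comp[v0] = 1;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        mem.push_back(v);
        for (size_t t = 0; t < adj[v].size(); ++t)
          if (comp[adj[v][t]] < 0) {
            comp[adj[v][t]] = 1;
            stack.push_back(adj[v][t]);
          }
      }
      comps.push_back(mem);
    }
    std::sort(comps.begin(), comps.end(),
              [](const std::vector<int> &a, const std::vector<int> &b) {
                return a.size() > b.size();
              });
  }

  // exact search for a clique of more than K vertices (which proves
  // infeasibility outright: every pair would need a distinct color);
  // branch-and-bound clique enumeration, pruned by the size target --
  // cheap because the sweep graphs are sparse
  bool clique_expand(int rsize, const std::vector<int> &P) const {
    if (rsize > K) return true;
    if (rsize + (int)P.size() <= K) return false;
    for (size_t idx = 0; idx < P.size(); ++idx) {
      int v = P[idx];
      if (rsize + (int)(P.size() - idx) <= K) return false;
      std::vector<int> P2;
      for (size_t t = idx + 1; t < P.size(); ++t)
        if (std::binary_search(adj[v].begin(), adj[v].end(), P[t]))
          P2.push_back(P[t]);
      if (clique_expand(rsize + 1, P2)) return true;
    }
    return false;
  }

  bool has_big_clique(const std::vector<int> &mem) const {
    std::vector<int> P(mem);
    std::sort(P.begin(), P.end());
    return clique_expand(0, P);
  }

  bool feasible_color(int v, int k) const {
    if (used[k] >= caps[k]) return false;
    for (size_t t = 0; t < adj[v].size(); ++t)
      if (color[adj[v][t]] == k) return false;
    return true;
  }

  // --- uncapacitated chromatic pre-test -----------------------------------
  // A witness of chromatic number > K survives in the K-core (outside it,
  // vertices of degree < K are always greedily colorable), so it suffices
  // to test plain K-colorability of the K-core, which is small and dense.
  std::vector<int> k_core(const std::vector<int> &mem) const {
    std::set<int> core(mem.begin(), mem.end());
    bool removed = true;
    while (removed) {
      removed = false;
      for (std::set<int>::iterator it = core.begin(); it != core.end();) {
        int deg = 0;
        for (size_t t = 0; t < adj[*it].size(); ++t)
          if (core.count(adj[*it][t])) ++deg;
        if (deg < K) { core.erase(it++); removed = true; }
        else ++it;
      }
    }
    return std::vector<int>(core.begin(), core.end());
  }

  bool plain_dfs(std::vector<int> &pcol, const std::vector<int> &verts,
                 const std::vector<int> &pos, int done, int maxUsed) {
    if (++nodes > node_limit) { budget_hit = true; return false; }
    if (done == (int)verts.size()) return true;
    // DSATUR pick among the restricted vertex set
    int best = -1, bestSat = -1, bestDeg = -1;
    std::vector<char> seen(K);
    for (size_t t = 0; t < verts.size(); ++t) {
      int v = verts[t];
      if (pcol[pos[v]] >= 0) continue;
      std::fill(seen.begin(), seen.end(), 0);
      int sat = 0, deg = 0;
      for (size_t s = 0; s < adj[v].size(); ++s) {
        int u = adj[v][s];
        if (pos[u] < 0) continue;
        ++deg;
        int cc = pcol[pos[u]];
        if (cc >= 0 && !seen[cc]) { seen[cc] = 1; ++sat; }
      }
      if (sat >= K) return false;
      if (sat > bestSat || (sat == bestSat && deg > bestDeg)) {
        best = v; bestSat = sat; bestDeg = deg;
      }
    }
    int v = best;
    std::fill(seen.begin(), seen.end(), 0);
    for (size_t s = 0; s < adj[v].size(); ++s) {
      int u = adj[v][s];
      if (pos[u] >= 0 && pcol[pos[u]] >= 0) seen[pcol[pos[u]]] = 1;
    }
    int kmax = std::min(K - 1, maxUsed + 1);  // colors interchangeable
    for (int k = 0; k <= kmax; ++k) {
      if (seen[k]) continue;
      pcol[pos[v]] = k;
      if (plain_dfs(pcol, verts, pos, done + 1, std::max(maxUsed, k)))
        return true;
      pcol[pos[v]] = -1;
      if (budget_hit) return false;
    }
    return false;
  }

  // randomized capacity-aware greedy passes over all components: DSATUR
  // order, each vertex takes an allowed color with maximal remaining
  // capacity (random ties).  A success certifies feasibility immediately;
  // failures mean nothing.  Uses R's RNG (caller holds RNGScope).
  bool greedy_feasible(int tries) {
    std::vector<int> all;
    for (size_t c = 0; c < comps.size(); ++c)
      all.insert(all.end(), comps[c].begin(), comps[c].end());
    std::vector<char> seen(K);
    for (int tr = 0; tr < tries; ++tr) {
      std::fill(color.begin(), color.end(), -1);
      std::fill(used.begin(), used.end(), 0);
      bool ok = true;
      for (size_t done = 0; done < all.size() && ok; ++done) {
        int best = -1, bestSat = -1, bestDeg = -1;
        for (size_t t = 0; t < all.size(); ++t) {
          int v = all[t];
          if (color[v] >= 0) continue;
          std::fill(seen.begin(), seen.end(), 0);
          int sat = 0;
          for (size_t s = 0; s < adj[v].size(); ++s) {
            int cc = color[adj[v][s]];
            if (cc >= 0 && !seen[cc]) { seen[cc] = 1; ++sat; }
          }
          if (sat > bestSat || (sat == bestSat && (int)adj[v].size() > bestDeg)) {
            best = v; bestSat = sat; bestDeg = (int)adj[v].size();
          }
        }
        std::fill(seen.begin(), seen.end(), 0);
        for (size_t s = 0; s < adj[best].size(); ++s)
          if (color[adj[best][s]] >= 0) seen[color[adj[best][s]]] = 1;
        int pickk = -1, bestRem = 0, nties = 0;
        for (int k = 0; k < K; ++k) {
          if (seen[k] || used[k] >= caps[k]) continue;
          int rem = caps[k] - used[k];
          if (rem > bestRem) { bestRem = rem; pickk = k; nties = 1; }
          else if (rem == bestRem && unif_rand() * ++nties < 1.0) pickk = k;
        }
        if (pickk < 0) { ok = false; break; }
        color[best] = pickk;
        ++used[pickk];
      }
      if (ok) return true;
    }
    std::fill(color.begin(), color.end(), -1);
    std::fill(used.begin(), used.end(), 0);
    return false;
  }

  // true when the component is provably not K-colorable at all
  bool chromatic_blocked(const std::vector<int> &mem) {
    std::vector<int> core = k_core(mem);
    if (core.empty()) return false;
    std::vector<int> pos(n, -1);
    for (size_t t = 0; t < core.size(); ++t) pos[core[t]] = (int)t;
    std::vector<int> pcol(core.size(), -1);
    bool colorable = plain_dfs(pcol, core, pos, 0, -1);
    return !colorable && !budget_hit;
  }

  bool solve_from(int c) {
    if (c == (int)comps.size()) return true;
    std::vector<int> rem(K);
    for (int k = 0; k < K; ++k) rem[k] = caps[k] - used[k];
    std::sort(rem.begin(), rem.end());
    std::pair<int, std::vector<int> > key(c, rem);
    if (failed.count(key)) return false;
    std::vector<int> save = usedInComp;
    std::fill(usedInComp.begin(), usedInComp.end(), 0);
    std::vector<std::vector<int> > parts(1, comps[c]);
    bool ok = dfs_parts(c, parts);
    usedInComp = save;
    if (!ok && !budget_hit) failed.insert(key);
    return ok;
  }

  // Search within component c, whose uncolored vertices currently form the
  // mutually non-adjacent `parts`.  Each node (a) fails if some uncolored
  // vertex has no allowed color or the vertices forced to a single color
  // exceed its remaining capacity, (b) unit-propagates forced vertices
  // first, and (c) otherwise branches on the vertex with maximal
  // saturation, re-splitting its part into connected sub-parts afterwards
  // (independent sub-parts interact only through the capacities).
  bool dfs_parts(int c, std::vector<std::vector<int> > &parts) {
    if (++nodes > node_limit) { budget_hit = true; return false; }
    while (!parts.empty() && parts.back().empty()) parts.pop_back();
    if (parts.empty()) return solve_from(c + 1);
    std::vector<int> demand(K, 0);
    int branch_v = -1, branch_part = -1, bestSat = -1, bestDeg = -1;
    int forced_v = -1, forced_part = -1, forced_k = -1;
    std::vector<char> seen(K);
    for (size_t pi = 0; pi < parts.size(); ++pi)
      for (size_t t = 0; t < parts[pi].size(); ++t) {
        int v = parts[pi][t];
        std::fill(seen.begin(), seen.end(), 0);
        int sat = 0;
        for (size_t s = 0; s < adj[v].size(); ++s) {
          int cc = color[adj[v][s]];
          if (cc >= 0 && !seen[cc]) { seen[cc] = 1; ++sat; }
        }
        int avail = 0, lastk = -1;
        for (int k = 0; k < K; ++k)
          if (!seen[k] && used[k] < caps[k]) { ++avail; lastk = k; }
        if (avail == 0) return false;          // dead vertex
        if (avail == 1) {
          ++demand[lastk];
          if (demand[lastk] > caps[lastk] - used[lastk]) return false;
          if (forced_v < 0) {
            forced_v = v; forced_part = (int)pi; forced_k = lastk;
          }
        }
        if (sat > bestSat || (sat == bestSat && (int)adj[v].size() > bestDeg)) {
          branch_v = v; branch_part = (int)pi;
          bestSat = sat; bestDeg = (int)adj[v].size();
        }
      }
    if (forced_v >= 0) { branch_v = forced_v; branch_part = forced_part; }
    std::vector<std::pair<int, int> > cand;
    if (forced_v >= 0) {
      cand.push_back(std::make_pair(0, forced_k));
    } else {
      for (int k = 0; k < K; ++k) {
        if (!feasible_color(branch_v, k)) continue;
        if (usedInComp[k] == 0) {
          bool shadowed = false;
          for (int k2 = 0; k2 < k; ++k2)
            if (usedInComp[k2] == 0 &&
                caps[k2] - used[k2] == caps[k] - used[k]) {
              shadowed = true;  // interchangeable with an earlier fresh color
              break;
            }
          if (shadowed) continue;
        }
        cand.push_back(std::make_pair(-(caps[k] - used[k]), k));
      }
      std::sort(cand.begin(), cand.end());
    }
    // remove the branch vertex from its part and pre-split the remainder
    // into connected sub-parts (colored vertices do not connect)
    std::vector<std::vector<int> > rest;
    for (size_t pi = 0; pi < parts.size(); ++pi)
      if ((int)pi != branch_part) rest.push_back(parts[pi]);
    split_connected(parts[branch_part], branch_v, rest);
    for (size_t t = 0; t < cand.size(); ++t) {
      int k = cand[t].second;
      color[branch_v] = k; ++used[k]; ++usedInComp[k];
      std::vector<std::vector<int> > next(rest);
      if (dfs_parts(c, next)) return true;  // keep the certificate intact
      color[branch_v] = -1; --used[k]; --usedInComp[k];
      if (budget_hit) return false;
    }
    return false;
  }

  // append the connected pieces of `part` minus vertex `out` to `dest`
  void split_connected(const std::vector<int> &part, int out,
                       std::vector<std::vector<int> > &dest) const {
    std::set<int> left(part.begin(), part.end());
    left.erase(out);
    while (!left.empty()) {
      std::vector<int> piece, stack(1, *left.begin());
      left.erase(left.begin());
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        piece.push_back(v);
        for (size_t s = 0; s < adj[v].size(); ++s) {
          int u = adj[v][s];
          std::set<int>::iterator it = left.find(u);
          if (it != left.end()) { left.erase(it); stack.push_back(u); }
        }
      }
      dest.push_back(piece);
    }
  }
};

// exact K = 2 case: bipartiteness + component orientation subset-sum
// status: 1 feasible, 0 infeasible
int solve_two_colors(int n, const std::vector<std::vector<int> > &adj,
                     const std::vector<int> &caps, std::vector<int> &color) {
  std::vector<int> comp(n, -1), side(n, -1);
  std::vector<std::pair<int, int> > counts;  // per component: (#side0, #side1)
  std::vector<std::vector<int> > members;
  int ncomp = 0;
  for (int v0 = 0; v0 < n; ++v0) {
    if (adj[v0].empty() || comp[v0] >= 0) continue;
    std::vector<int> queue(1, v0);
    comp[v0] = ncomp; side[v0] = 0;
    int c0 = 0, c1 = 0;
    std::vector<int> mem;
    while (!queue.empty()) {
      int v = queue.back(); queue.pop_back();
      mem.push_back(v);
      if (side[v] == 0) ++c0; else ++c1;
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int u = adj[v][t];
        if (comp[u] < 0) {
          comp[u] = ncomp; side[u] = 1 - side[v];
          queue.push_back(u);
        } else if (side[u] == side[v]) {
          return 0;  // odd cycle
        }
      }
    }
    counts.push_back(std::make_pair(c0, c1));
    members.push_back(mem);
    ++ncomp;
  }
  // choose per component which side gets color 0 so that total usage fits
  int cap0 = caps[0], cap1 = caps[1];
  int total = 0;
  for (int c = 0; c < ncomp; ++c) total += counts[c].first + counts[c].second;
  // reachable[s] after processing components 0..c-1, s = usage of color 0
  std::vector<std::vector<char> > reach(ncomp + 1, std::vector<char>(cap0 + 1, 0));
  reach[0][0] = 1;
  for (int c = 0; c < ncomp; ++c)
    for (int s = 0; s <= cap0; ++s) {
      if (!reach[c][s]) continue;
      if (s + counts[c].first <= cap0) reach[c + 1][s + counts[c].first] = 1;
      if (s + counts[c].second <= cap0) reach[c + 1][s + counts[c].second] = 1;
    }
  int goal = -1;
  for (int s = 0; s <= cap0; ++s)
    if (reach[ncomp][s] && total - s <= cap1) { goal = s; break; }
  if (goal < 0) return 0;
  // reconstruct orientations backwards
  std::vector<int> flip(ncomp);
  int s = goal;
  for (int c = ncomp - 1; c >= 0; --c) {
    int a = counts[c].first, b = counts[c].second;
    if (s - a >= 0 && reach[c][s - a]) { flip[c] = 0; s -= a; }
    else { flip[c] = 1; s -= b; }
  }
  for (int c = 0; c < ncomp; ++c)
    for (size_t t = 0; t < members[c].size(); ++t) {
      int v = members[c][t];
      color[v] = flip[c] ? (1 - side[v]) : side[v];
    }
  return 1;
}

}  // namespace

// status: 1 feasible, 0 infeasible, -1 node budget exceeded.
// edges is a 2-column matrix of 0-based vertex pairs.
// [[Rcpp::export]]
List color_bounded_cpp(int n, IntegerMatrix edges, int K, IntegerVector caps,
                       double node_limit) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  for (int v = 0; v < n; ++v) {  // canonical order: input edge order is moot
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<int> color(n, -1);
  int status;
  if (K == 2) {
    std::vector<int> cp(caps.begin(), caps.end());
    status = solve_two_colors(n, adj, cp, color);
  } else {
    ColorProblem pb;
    pb.n = n; pb.K = K;
    pb.adj = adj;
    pb.caps.assign(caps.begin(), caps.end());
    pb.color.assign(n, -1);
    pb.used.assign(K, 0);
    pb.usedInComp.assign(K, 0);
    pb.nodes = 0; pb.node_limit = node_limit; pb.budget_hit = false;
    pb.build_components();
    bool ok = pb.greedy_feasible(32);
    if (!ok) {
      bool blocked = false;
      for (size_t c = 0; c < pb.comps.size() && !blocked && !pb.budget_hit;
           ++c)
        blocked = pb.has_big_clique(pb.comps[c]) ||
                  pb.chromatic_blocked(pb.comps[c]);
      ok = !blocked && !pb.budget_hit && pb.solve_from(0);
    }
    if (pb.budget_hit) status = -1;
    else status = ok ? 1 : 0;
    if (status == 1) color = pb.color;
  }
  IntegerVector out(n, NA_INTEGER);
  if (status == 1)
    for (int v = 0; v < n; ++v)
      if (color[v] >= 0) out[v] = color[v] + 1;  // 1-based, NA = unassigned
  return List::create(_["status"] = status, _["coloring"] = out);
}

// ---------------------------------------------------------------------------
// Exact maximum diversity under cardinality constraints.
//
// Depth-first branch and bound over assignments in object order.  An upper
// bound adds to the current within-group sum the F largest pairwise values
// in the whole matrix, where F is the number of within-group pairs still to
// be formed; this is valid for raw and penalty-adjusted matrices alike.
// Clusters of equal target size are interchangeable, so an object may only
// open the first empty cluster within each size class.
// ---------------------------------------------------------------------------

namespace {

struct DivProblem {
  int n, K;
  const double *d;  // column-major n x n
  std::vector<int> sizes, cnt, assign, best_assign;
  std::vector<double> prefix;  // prefix sums of all pair values, descending
  double best;
  double nodes, node_limit;
  bool budget_hit;
  int total_pairs_within;

  int pairs_now() const {
    int p = 0;
    for (int k = 0; k < K; ++k) p += cnt[k] * (cnt[k] - 1) / 2;
    return p;
  }

  void solve(int v, double cur, int curPairs) {
    if (++nodes > node_limit) { budget_hit = true; return; }
    if (v == n) {
      if (cur > best) { best = cur; best_assign = assign; }
      return;
    }
    int F = total_pairs_within - curPairs;
    if (cur + prefix[F] <= best) return;  // cannot beat incumbent
    // candidate clusters ordered by gain (descending) for fast incumbents
    std::vector<std::pair<double, int> > cand;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] >= sizes[k]) continue;
      if (cnt[k] == 0) {
        bool firstEmpty = true;
        for (int k2 = 0; k2 < k; ++k2)
          if (cnt[k2] == 0 && sizes[k2] == sizes[k]) { firstEmpty = false; break; }
        if (!firstEmpty) continue;
      }
      double gain = 0;
      for (int u = 0; u < v; ++u)
        if (assign[u] == k) gain += d[u + (size_t)n * v];
      cand.push_back(std::make_pair(-gain, k));
    }
    std::sort(cand.begin(), cand.end());
    for (size_t t = 0; t < cand.size(); ++t) {
      int k = cand[t].second;
      double gain = -cand[t].first;
      assign[v] = k; ++cnt[k];
      solve(v + 1, cur + gain, curPairs + cnt[k] - 1);
      --cnt[k]; assign[v] = -1;
      if (budget_hit) return;
    }
  }
};

}  // namespace

// status: 1 optimal, -1 node budget exceeded (best incumbent still returned).
// [[Rcpp::export]]
List max_diversity_bb_cpp(NumericMatrix D, IntegerVector sizes,
                          double node_limit) {
  DivProblem pb;
  pb.n = D.nrow();
  pb.K = sizes.size();
  pb.d = REAL(D);
  pb.sizes.assign(sizes.begin(), sizes.end());
  pb.cnt.assign(pb.K, 0);
  pb.assign.assign(pb.n, -1);
  pb.best = -std::numeric_limits<double>::infinity();
  pb.nodes = 0; pb.node_limit = node_limit; pb.budget_hit = false;
  pb.total_pairs_within = 0;
  for (int k = 0; k < pb.K; ++k)
    pb.total_pairs_within += pb.sizes[k] * (pb.sizes[k] - 1) / 2;
  std::vector<double> vals;
  vals.reserve((size_t)pb.n * (pb.n - 1) / 2);
  for (int i = 0; i < pb.n; ++i)
    for (int j = i + 1; j < pb.n; ++j)
      vals.push_back(pb.d[i + (size_t)pb.n * j]);
  std::sort(vals.begin(), vals.end(), std::greater<double>());
  pb.prefix.assign(vals.size() + 1, 0);
  for (size_t t = 0; t < vals.size(); ++t)
    pb.prefix[t + 1] = pb.prefix[t] + vals[t];
  pb.solve(0, 0.0, 0);
  IntegerVector out(pb.n, NA_INTEGER);
  if (!pb.best_assign.empty())
    for (int v = 0; v < pb.n; ++v) out[v] = pb.best_assign[v] + 1;
  return List::create(_["status"] = pb.budget_hit ? -1 : 1,
                      _["assignment"] = out,
                      _["value"] = pb.best,
                      _["nodes"] = pb.nodes);
}
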
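#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bicriterion pairwise-interchange machinery.
//
// The engine maintains, for the current partition:
//   * sumdiv[v*K+k]  : sum of diversity-matrix entries from v to cluster k
//   * W[k]           : within-cluster diversity sums
//   * a sorted list of within-cluster pairs of the dispersion matrix
//   * min1/min2[v*K+k]: two smallest dispersion-matrix entries from v into
//                       cluster k (with the argmin of the smallest)
// so that a candidate pairwise exchange is scored in O(1) amortized:
// the diversity delta from the cached sums, the new dispersion as the
// minimum of (smallest surviving within pair, new pairs formed by the two
// moved objects).  Exchanges use best-improvement per focal object with
// ties broken by the lowest partner index.  All randomness is drawn from
// R's RNG so that set.seed() governs full runs.
// ---------------------------------------------------------------------------

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline double wscore(double w, double dv, double ds) {
  if (w >= 1.0) return dv;
  if (w <= 0.0) return ds;
  return w * dv + (1.0 - w) * ds;
}

std::vector<int> canonical_form(const std::vector<int> &a, int K) {
  std::vector<int> map(K, -1), out(a.size());
  int next = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (map[a[i]] < 0) map[a[i]] = next++;
    out[i] = map[a[i]];
  }
  return out;
}

struct ParetoStore {
  std::vector<std::vector<int> > parts;  // canonical, 0-based
  std::vector<double> divs, disps;

  // cand scores must be exact (recomputed from the matrices)
  void insert_exact(const std::vector<int> &canon, double dv, double ds) {
    for (size_t e = 0; e < parts.size(); ++e) {
      bool geq = divs[e] >= dv && disps[e] >= ds;
      bool strict = divs[e] > dv || disps[e] > ds;
      if (geq && strict) return;                       // dominated
      if (divs[e] == dv && disps[e] == ds && parts[e] == canon) return;  // dup
    }
    size_t keep = 0;
    for (size_t e = 0; e < parts.size(); ++e) {
      bool dominated = dv >= divs[e] && ds >= disps[e] &&
                       (dv > divs[e] || ds > disps[e]);
      if (!dominated) {
        if (keep != e) {
          parts[keep] = parts[e]; divs[keep] = divs[e]; disps[keep] = disps[e];
        }
        ++keep;
      }
    }
    parts.resize(keep); divs.resize(keep); disps.resize(keep);
    parts.push_back(canon); divs.push_back(dv); disps.push_back(ds);
  }

  // quick reject using (possibly incrementally maintained) scores
  bool worth_trying(double dv, double ds) const {
    for (size_t e = 0; e < parts.size(); ++e)
      if (divs[e] >= dv && disps[e] >= ds && (divs[e] > dv || disps[e] > ds))
        return false;
    return true;
  }
};

struct PairRec {
  double d; int i, j;
  bool operator<(const PairRec &o) const {
    if (d != o.d) return d < o.d;
    if (i != o.i) return i < o.i;
    return j < o.j;
  }
};

struct Engine {
  int n, K, crit;  // crit: 0 = diversity, 1 = average diversity
  const double *dd, *dp;
  std::vector<int> sizes, a;
  std::vector<double> sumdiv, W;
  double objdiv;
  std::vector<PairRec> within;
  std::vector<double> m1, m2;
  std::vector<int> m1arg;
  double disp;

  void setup(const NumericMatrix &Ddiv, const NumericMatrix &Ddisp,
             const IntegerVector &sz, int criterion) {
    n = Ddiv.nrow(); K = sz.size(); crit = criterion;
    dd = REAL(Ddiv); dp = REAL(Ddisp);
    sizes.assign(sz.begin(), sz.end());
    sumdiv.assign((size_t)n * K, 0.0);
    W.assign(K, 0.0);
    m1.assign((size_t)n * K, INF);
    m2.assign((size_t)n * K, INF);
    m1arg.assign((size_t)n * K, -1);
  }

  double obj_from_W() const {
    double s = 0;
    for (int k = 0; k < K; ++k) s += crit ? W[k] / sizes[k] : W[k];
    return s;
  }

  void init(const std::vector<int> &assign) {
    a = assign;
    std::fill(sumdiv.begin(), sumdiv.end(), 0.0);
    std::fill(W.begin(), W.end(), 0.0);
    for (int v = 0; v < n; ++v)
      for (int u = 0; u < n; ++u)
        if (u != v) sumdiv[(size_t)v * K + a[u]] += dd[v + (size_t)n * u];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (a[i] == a[j]) W[a[i]] += dd[i + (size_t)n * j];
    objdiv = obj_from_W();
    rebuild_within();
    for (int k = 0; k < K; ++k) rebuild_min(k);
  }

  void rebuild_within() {
    within.clear();
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (a[i] == a[j]) {
          PairRec r; r.d = dp[i + (size_t)n * j]; r.i = i; r.j = j;
          within.push_back(r);
        }
    std::sort(within.begin(), within.end());
    disp = within.empty() ? INF : within[0].d;
  }

  void rebuild_min(int k) {
    for (int v = 0; v < n; ++v) {
      double b1 = INF, b2 = INF; int arg = -1;
      for (int u = 0; u < n; ++u) {
        if (u == v || a[u] != k) continue;
        double x = dp[v + (size_t)n * u];
        if (x < b1) { b2 = b1; b1 = x; arg = u; }
        else if (x < b2) b2 = x;
      }
      m1[(size_t)v * K + k] = b1;
      m2[(size_t)v * K + k] = b2;
      m1arg[(size_t)v * K + k] = arg;
    }
  }

  // evaluate exchanging objects i and j (must be in different clusters)
  double eval(int i, int j, double w, double &ndiv, double &ndisp) const {
    int A = a[i], B = a[j];
    double dij = dd[i + (size_t)n * j];
    double dWA = sumdiv[(size_t)j * K + A] - dij - sumdiv[(size_t)i * K + A];
    double dWB = sumdiv[(size_t)i * K + B] - dij - sumdiv[(size_t)j * K + B];
    ndiv = crit ? objdiv + dWA / sizes[A] + dWB / sizes[B]
                : objdiv + dWA + dWB;
    double base = INF;
    for (size_t t = 0; t < within.size(); ++t) {
      const PairRec &r = within[t];
      if (r.i != i && r.i != j && r.j != i && r.j != j) { base = r.d; break; }
    }
    double mi = (m1arg[(size_t)i * K + B] == j) ? m2[(size_t)i * K + B]
                                                : m1[(size_t)i * K + B];
    double mj = (m1arg[(size_t)j * K + A] == i) ? m2[(size_t)j * K + A]
                                                : m1[(size_t)j * K + A];
    ndisp = std::min(base, std::min(mi, mj));
    return wscore(w, ndiv, ndisp);
  }

  void apply(int i, int j) {
    int A = a[i], B = a[j];
    double dij = dd[i + (size_t)n * j];
    W[A] += sumdiv[(size_t)j * K + A] - dij - sumdiv[(size_t)i * K + A];
    W[B] += sumdiv[(size_t)i * K + B] - dij - sumdiv[(size_t)j * K + B];
    for (int v = 0; v < n; ++v) {
      double di = dd[v + (size_t)n * i], dj = dd[v + (size_t)n * j];
      sumdiv[(size_t)v * K + A] += dj - di;
      sumdiv[(size_t)v * K + B] += di - dj;
    }
    a[i] = B; a[j] = A;
    objdiv = obj_from_W();
    rebuild_within();
    rebuild_min(A);
    rebuild_min(B);
  }

  // exact rescoring (independent of the incremental bookkeeping)
  double exact_div(const std::vector<int> &x) const {
    std::vector<double> ws(K, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (x[i] == x[j]) ws[x[i]] += dd[i + (size_t)n * j];
    double s = 0;
    std::vector<int> cnt(K, 0);
    for (int i = 0; i < n; ++i) ++cnt[x[i]];
    for (int k = 0; k < K; ++k) s += crit ? (cnt[k] ? ws[k] / cnt[k] : 0.0) : ws[k];
    return s;
  }
  double exact_disp(const std::vector<int> &x) const {
    double m = INF;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (x[i] == x[j]) m = std::min(m, dp[i + (size_t)n * j]);
    return m;
  }

  void record(ParetoStore *store) const {
    if (!store) return;
    if (!store->worth_trying(objdiv, disp)) return;
    std::vector<int> canon = canonical_form(a, K);
    store->insert_exact(canon, exact_div(a), exact_disp(a));
  }

  // best-improvement pairwise interchange until local optimality
  void bpi(double w, ParetoStore *store) {
    record(store);
    bool improved = true;
    while (improved) {
      improved = false;
      for (int i = 0; i < n; ++i) {
        double cur = wscore(w, objdiv, disp);
        double best = cur, bdiv = 0, bdisp = 0;
        int bestj = -1;
        for (int j = 0; j < n; ++j) {
          if (a[j] == a[i]) continue;
          double ndiv, ndisp;
          double sc = eval(i, j, w, ndiv, ndisp);
          if (sc > best) { best = sc; bestj = j; bdiv = ndiv; bdisp = ndisp; }
        }
        if (bestj >= 0) {
          apply(i, bestj);
          improved = true;
          record(store);
        }
      }
    }
  }
};

void perturb_pairs(std::vector<int> &a, double p) {
  int n = (int)a.size();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a[i] != a[j] && unif_rand() < p) std::swap(a[i], a[j]);
}

std::vector<int> to0(const IntegerVector &x) {
  std::vector<int> a(x.size());
  for (int i = 0; i < x.size(); ++i) a[i] = x[i] - 1;
  return a;
}

List store_to_list(const ParetoStore &st) {
  int m = (int)st.parts.size();
  List parts(m);
  NumericVector dv(m), ds(m);
  for (int e = 0; e < m; ++e) {
    IntegerVector p(st.parts[e].size());
    for (size_t i = 0; i < st.parts[e].size(); ++i) p[i] = st.parts[e][i] + 1;
    parts[e] = p;
    dv[e] = st.divs[e];
    ds[e] = st.disps[e];
  }
  return List::create(_["partitions"] = parts, _["diversity"] = dv,
                      _["dispersion"] = ds);
}

}  // namespace

// Full BILS: phase 1 runs one BPI per row of `inits` (weights drawn from the
// catalog per restart); phase 2 runs `ils_restarts` iterations of perturb +
// BPI starting from uniformly chosen Pareto entries.
// [[Rcpp::export]]
List bils_cpp(NumericMatrix ddiv, NumericMatrix ddisp, IntegerVector sizes,
              IntegerMatrix inits, int ils_restarts, NumericVector wcat,
              double pmin, double pmax, int crit) {
  Engine eng;
  eng.setup(ddiv, ddisp, sizes, crit);
  ParetoStore store;
  int nw = wcat.size();
  for (int r = 0; r < inits.nrow(); ++r) {
    double w = wcat[(int)(unif_rand() * nw) % nw];
    std::vector<int> a(inits.ncol());
    for (int i = 0; i < inits.ncol(); ++i) a[i] = inits(r, i) - 1;
    eng.init(a);
    eng.bpi(w, &store);
  }
  for (int t = 0; t < ils_restarts; ++t) {
    if (store.parts.empty()) break;
    int idx = (int)(unif_rand() * store.parts.size()) % store.parts.size();
    std::vector<int> a = store.parts[idx];
    double p = pmin + unif_rand() * (pmax - pmin);
    perturb_pairs(a, p);
    double w = wcat[(int)(unif_rand() * nw) % nw];
    eng.init(a);
    eng.bpi(w, &store);
  }
  return store_to_list(store);
}

// Single BPI run from a given start, threading an existing Pareto set.
// [[Rcpp::export]]
List bpi_cpp(NumericMatrix ddiv, NumericMatrix ddisp, IntegerVector sizes,
             IntegerVector init, double w, int crit, List pareto_partitions,
             NumericVector pareto_div, NumericVector pareto_disp) {
  Engine eng;
  eng.setup(ddiv, ddisp, sizes, crit);
  ParetoStore store;
  for (int e = 0; e < pareto_partitions.size(); ++e) {
    IntegerVector p = pareto_partitions[e];
    store.parts.push_back(canonical_form(to0(p), sizes.size()));
    store.divs.push_back(pareto_div[e]);
    store.disps.push_back(pareto_disp[e]);
  }
  eng.init(to0(init));
  eng.bpi(w, &store);
  IntegerVector fin(eng.n);
  for (int i = 0; i < eng.n; ++i) fin[i] = eng.a[i] + 1;
  List out = store_to_list(store);
  out["final"] = fin;
  return out;
}

// Plain local search (LCW): best-improvement interchange on one criterion.
// [[Rcpp::export]]
IntegerVector lcw_cpp(NumericMatrix dd, IntegerVector sizes,
                      IntegerVector init, int crit) {
  Engine eng;
  eng.setup(dd, dd, sizes, crit);
  eng.init(to0(init));
  eng.bpi(1.0, 0);
  IntegerVector fin(eng.n);
  for (int i = 0; i < eng.n; ++i) fin[i] = eng.a[i] + 1;
  return fin;
}

// Pair-swap perturbation in fixed index order, i.i.d. probability p.
// [[Rcpp::export]]
IntegerVector ils_perturb_cpp(IntegerVector clusters, double p) {
  std::vector<int> a = to0(clusters);
  perturb_pairs(a, p);
  IntegerVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) out[i] = a[i] + 1;
  return out;
}
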
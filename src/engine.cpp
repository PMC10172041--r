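// Sparse inside-outside engine for simultaneous alignment and folding.
//
// All dynamic programs (pairwise SAF ensemble, single-sequence structure
// ensemble, and the degenerate pair-HMM obtained when no base pairs are
// allowed) are expressed as acyclic hypergraphs: nodes are DP states, each
// hyperedge carries the scoring features it emits, and edge weight is
// exp(theta . counts).  One generic log-domain sweep then provides the
// partition function, outside values, expected feature counts, event
// posteriors and stochastic traceback for every grammar.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include "catalog.h"

using namespace Rcpp;
using cf::ST_M; using cf::ST_I; using cf::ST_D;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// ---------------------------------------------------------------------------
// generic hypergraph
// ---------------------------------------------------------------------------

struct Graph {
  int nnodes = 0;
  std::vector<int> head, t1, t2, t3;
  std::vector<int> fptr;          // CSR over feature emissions
  std::vector<int> fid;
  std::vector<double> fcnt;
  std::vector<int> evm1, evm2;    // match-event ids (rows of AM), -1 if none
  std::vector<int> evq;           // quadruple / pair event id, -1 if none
  std::vector<int> cf_; std::vector<double> cc_;  // emission staging

  std::vector<int> eorder;        // edges sorted by topological rank of head

  Graph() { fptr.push_back(0); }
  int nn() { return nnodes++; }
  int nedges() const { return (int)head.size(); }
  void f(int id, double c) { cf_.push_back(id); cc_.push_back(c); }
  void edge(int h, int a = -1, int b = -1, int c = -1,
            int m1 = -1, int m2 = -1, int q = -1) {
    head.push_back(h); t1.push_back(a); t2.push_back(b); t3.push_back(c);
    evm1.push_back(m1); evm2.push_back(m2); evq.push_back(q);
    for (size_t i = 0; i < cf_.size(); ++i) { fid.push_back(cf_[i]); fcnt.push_back(cc_[i]); }
    fptr.push_back((int)fid.size());
    cf_.clear(); cc_.clear();
  }
};

struct Sweep {
  std::vector<double> ins, out, elogw;
  double logz_in = NEG_INF, logz_out = NEG_INF;
};

// topological edge order (by head rank); depends only on the graph, so it
// is computed once at build time and reused across theta evaluations
static void finalize_graph(Graph& g) {
  int ne = g.nedges();
  std::vector<int> indeg(g.nnodes, 0), outcnt(g.nnodes, 0);
  for (int e = 0; e < ne; ++e) {
    if (g.t1[e] >= 0) { indeg[g.head[e]]++; outcnt[g.t1[e]]++; }
    if (g.t2[e] >= 0) { indeg[g.head[e]]++; outcnt[g.t2[e]]++; }
    if (g.t3[e] >= 0) { indeg[g.head[e]]++; outcnt[g.t3[e]]++; }
  }
  std::vector<int> aptr(g.nnodes + 1, 0);
  for (int n = 0; n < g.nnodes; ++n) aptr[n + 1] = aptr[n] + outcnt[n];
  std::vector<int> adj(aptr[g.nnodes]);
  std::vector<int> fill(g.nnodes, 0);
  for (int e = 0; e < ne; ++e) {
    int ts[3] = {g.t1[e], g.t2[e], g.t3[e]};
    for (int s2 = 0; s2 < 3; ++s2) if (ts[s2] >= 0) adj[aptr[ts[s2]] + fill[ts[s2]]++] = e;
  }
  std::vector<int> rank(g.nnodes, -1), queue;
  queue.reserve(g.nnodes);
  for (int n = 0; n < g.nnodes; ++n) if (indeg[n] == 0) queue.push_back(n);
  int qh = 0, r = 0;
  while (qh < (int)queue.size()) {
    int n = queue[qh++];
    rank[n] = r++;
    for (int a = aptr[n]; a < aptr[n + 1]; ++a) {
      int e = adj[a];
      if (--indeg[g.head[e]] == 0) queue.push_back(g.head[e]);
    }
  }
  if (r != g.nnodes) stop("internal error: DP hypergraph is cyclic");
  g.eorder.resize(ne);
  for (int e = 0; e < ne; ++e) g.eorder[e] = e;
  std::sort(g.eorder.begin(), g.eorder.end(),
            [&](int a, int b) { return rank[g.head[a]] < rank[g.head[b]]; });
}

static void run_inside(const Graph& g, const std::vector<double>& theta, Sweep& s) {
  int ne = g.nedges();
  s.elogw.assign(ne, 0.0);
  for (int e = 0; e < ne; ++e) {
    double w = 0.0;
    for (int k = g.fptr[e]; k < g.fptr[e + 1]; ++k) w += theta[g.fid[k]] * g.fcnt[k];
    s.elogw[e] = w;
  }
  s.ins.assign(g.nnodes, NEG_INF);
  for (int e : g.eorder) {
    double v = s.elogw[e];
    if (g.t1[e] >= 0) v += s.ins[g.t1[e]];
    if (g.t2[e] >= 0) v += s.ins[g.t2[e]];
    if (g.t3[e] >= 0) v += s.ins[g.t3[e]];
    s.ins[g.head[e]] = lse2(s.ins[g.head[e]], v);
  }
}

static void run_outside(const Graph& g, Sweep& s, int final_node, int start_node) {
  s.out.assign(g.nnodes, NEG_INF);
  s.out[final_node] = 0.0;
  for (int k = g.nedges() - 1; k >= 0; --k) {
    int e = g.eorder[k];
    double base = s.out[g.head[e]];
    if (base == NEG_INF) continue;
    base += s.elogw[e];
    int ts[3] = {g.t1[e], g.t2[e], g.t3[e]};
    double iv[3];
    for (int i = 0; i < 3; ++i) iv[i] = ts[i] >= 0 ? s.ins[ts[i]] : 0.0;
    for (int i = 0; i < 3; ++i) {
      if (ts[i] < 0) continue;
      double add = base;
      for (int j2 = 0; j2 < 3; ++j2) if (j2 != i) add += iv[j2];
      if (add != NEG_INF) s.out[ts[i]] = lse2(s.out[ts[i]], add);
    }
  }
  s.logz_out = s.out[start_node] + s.ins[start_node];
}

// expected feature counts + event posteriors
static void accumulate(const Graph& g, const Sweep& s, double logz,
                       std::vector<double>* ecounts,
                       std::vector<double>* pmatch,
                       std::vector<double>* pquad_edge) {
  for (int e = 0; e < g.nedges(); ++e) {
    double lp = s.out[g.head[e]];
    if (lp == NEG_INF) continue;
    lp += s.elogw[e] - logz;
    if (g.t1[e] >= 0) lp += s.ins[g.t1[e]];
    if (g.t2[e] >= 0) lp += s.ins[g.t2[e]];
    if (g.t3[e] >= 0) lp += s.ins[g.t3[e]];
    if (lp == NEG_INF) continue;
    double p = std::exp(lp);
    if (ecounts)
      for (int k = g.fptr[e]; k < g.fptr[e + 1]; ++k) (*ecounts)[g.fid[k]] += p * g.fcnt[k];
    if (pmatch) {
      if (g.evm1[e] >= 0) (*pmatch)[g.evm1[e]] += p;
      if (g.evm2[e] >= 0) (*pmatch)[g.evm2[e]] += p;
    }
    if (pquad_edge && g.evq[e] >= 0) (*pquad_edge)[g.evq[e]] += p;
  }
}

// stochastic traceback: one derivation, records match/quad event ids
static void sample_one(const Graph& g, const Sweep& s,
                       const std::vector<int>& inptr, const std::vector<int>& inedges,
                       int final_node,
                       std::vector<int>& matches, std::vector<int>& quads) {
  std::vector<int> stack;
  stack.push_back(final_node);
  while (!stack.empty()) {
    int n = stack.back(); stack.pop_back();
    int lo = inptr[n], hi = inptr[n + 1];
    if (lo == hi) continue;   // leaf with no incoming edges
    double u = unif_rand();
    double acc = 0.0;
    int chosen = inedges[hi - 1];
    for (int a = lo; a < hi; ++a) {
      int e = inedges[a];
      double v = s.elogw[e];
      if (g.t1[e] >= 0) v += s.ins[g.t1[e]];
      if (g.t2[e] >= 0) v += s.ins[g.t2[e]];
      if (g.t3[e] >= 0) v += s.ins[g.t3[e]];
      acc += std::exp(v - s.ins[n]);
      if (u <= acc) { chosen = e; break; }
    }
    if (g.evm1[chosen] >= 0) matches.push_back(g.evm1[chosen]);
    if (g.evm2[chosen] >= 0) matches.push_back(g.evm2[chosen]);
    if (g.evq[chosen] >= 0) quads.push_back(g.evq[chosen]);
    if (g.t1[chosen] >= 0) stack.push_back(g.t1[chosen]);
    if (g.t2[chosen] >= 0) stack.push_back(g.t2[chosen]);
    if (g.t3[chosen] >= 0) stack.push_back(g.t3[chosen]);
  }
}

// ---------------------------------------------------------------------------
// joint pairwise SAF grammar
// ---------------------------------------------------------------------------

// per-sequence one-branch loop features (stack / bulge / internal) emitted
// at the closure of an outer pair around a single inner pair
static void one_branch_feats(Graph& g, const std::vector<int>& seq,
                             int i, int i2, int j2, int j) {
  int a = i2 - i - 1, b = j - j2 - 1;
  if (a == 0 && b == 0) {
    int outer = cf::canon_idx(seq[i], seq[j]);
    int inner = cf::canon_idx(seq[i2], seq[j2]);
    if (outer >= 0 && inner >= 0) g.f(cf::OFF_STACK + outer * 6 + inner, 1);
  } else if (a == 0 || b == 0) {
    g.f(cf::bulge_idx(a + b), 1);
  } else {
    g.f(cf::int_idx(a + b), 1);
    g.f(cf::asym_idx(std::abs(a - b)), 1);
  }
}

struct Quad { int i, j, k, l, amL, amR, pxrow, pyrow; };

struct GAnchor { int p, q, extJ, extL, base, gmbase, sj, sl; };
struct FAnchor { int p, q, extJ, extL, base, mbase, sj, sl; };

struct JointGraph {
  Graph g;
  int N, M, start_node, final_node;
  std::vector<Quad> quads;
  int nmatch;
};

// E-state encoding: t = 0 begin, 1 M, 2 I, 3 D; feature state code = t - 1
static inline int est(int t) { return t - 1; }

static void build_joint(JointGraph& J,
                        const std::vector<int>& xs, const std::vector<int>& ys,
                        const IntegerMatrix& am, const IntegerMatrix& px,
                        const IntegerMatrix& py, int min_hairpin) {
  Graph& g = J.g;
  int N = J.N = (int)xs.size() - 1;   // sequences are 1-based with dummy [0]
  int M = J.M = (int)ys.size() - 1;
  int nm = am.nrow();
  J.nmatch = nm;

  auto key = [M](int i, int k) { return (long long)i * (M + 2) + k; };
  std::unordered_map<long long, int> amid;
  amid.reserve(nm * 2);
  for (int r = 0; r < nm; ++r) amid[key(am(r, 0), am(r, 1))] = r;

  // consistent quadruples
  std::vector<Quad>& Q = J.quads;
  for (int a = 0; a < px.nrow(); ++a) {
    for (int b = 0; b < py.nrow(); ++b) {
      int i = px(a, 0), j = px(a, 1), k = py(b, 0), l = py(b, 1);
      auto itL = amid.find(key(i, k)), itR = amid.find(key(j, l));
      if (itL == amid.end() || itR == amid.end()) continue;
      Q.push_back({i, j, k, l, itL->second, itR->second, a, b});
    }
  }
  int nq = (int)Q.size();

  // G anchors: left ends of quadruples and right ends used inside another
  // quadruple; FM anchors: left ends only
  std::unordered_map<long long, int> gmap, fmap;
  std::vector<GAnchor> GA;
  std::vector<FAnchor> FA;
  auto touch_g = [&](int p, int q, int eJ, int eL) {
    auto it = gmap.find(key(p, q));
    if (it == gmap.end()) {
      gmap[key(p, q)] = (int)GA.size();
      GA.push_back({p, q, eJ, eL, 0, 0, 0, 0});
    } else {
      GAnchor& a = GA[it->second];
      if (eJ > a.extJ) a.extJ = eJ;
      if (eL > a.extL) a.extL = eL;
    }
  };
  auto touch_f = [&](int p, int q, int eJ, int eL) {
    auto it = fmap.find(key(p, q));
    if (it == fmap.end()) {
      fmap[key(p, q)] = (int)FA.size();
      FA.push_back({p, q, eJ, eL, 0, 0, 0, 0});
    } else {
      FAnchor& a = FA[it->second];
      if (eJ > a.extJ) a.extJ = eJ;
      if (eL > a.extL) a.extL = eL;
    }
  };
  std::vector<std::vector<int>> nested(nq);   // nested[outer] = inner ids
  for (int o = 0; o < nq; ++o) {
    touch_g(Q[o].i, Q[o].k, Q[o].j - 1, Q[o].l - 1);
    touch_f(Q[o].i, Q[o].k, Q[o].j - 1, Q[o].l - 1);
    for (int in2 = 0; in2 < nq; ++in2) {
      if (Q[o].i < Q[in2].i && Q[in2].j < Q[o].j &&
          Q[o].k < Q[in2].k && Q[in2].l < Q[o].l) {
        nested[o].push_back(in2);
        touch_g(Q[in2].j, Q[in2].l, Q[o].j - 1, Q[o].l - 1);
      }
    }
  }

  // node allocation
  int e_base = 0;
  g.nnodes = (N + 1) * (M + 1) * 4;
  int em_base = g.nnodes; g.nnodes += (N + 1) * (M + 1);
  int final_node = g.nn();
  for (auto& a : GA) {
    a.sj = a.extJ - a.p + 1; a.sl = a.extL - a.q + 1;
    if (a.sj < 1) a.sj = 1;
    if (a.sl < 1) a.sl = 1;
    a.base = g.nnodes; g.nnodes += a.sj * a.sl * 3;
    a.gmbase = g.nnodes; g.nnodes += a.sj * a.sl;
  }
  // a multibranch interior needs at least two branches of span
  // min_hairpin+2 each; anchors whose extent cannot hold them would carry
  // FM tables that are identically -inf, so they are skipped outright
  const int need = 2 * (min_hairpin + 2);
  for (auto& a : FA) {
    a.sj = a.extJ - a.p + 1; a.sl = a.extL - a.q + 1;
    if (a.sj < 1) a.sj = 1;
    if (a.sl < 1) a.sl = 1;
    if (a.extJ - a.p < need || a.extL - a.q < need) { a.base = -1; a.mbase = -1; continue; }
    a.base = g.nnodes; g.nnodes += 3 * a.sj * a.sl * 3;
    a.mbase = g.nnodes; g.nnodes += 3 * a.sj * a.sl;
  }
  int aq_base = g.nnodes; g.nnodes += nq;

  auto E = [&](int j, int l, int t) { return e_base + (j * (M + 1) + l) * 4 + t; };
  auto EM = [&](int j, int l) { return em_base + j * (M + 1) + l; };
  auto Gc = [&](const GAnchor& a, int j, int l, int t) {
    return a.base + ((j - a.p) * a.sl + (l - a.q)) * 3 + t;
  };
  auto GMc = [&](const GAnchor& a, int j, int l) {
    return a.gmbase + (j - a.p) * a.sl + (l - a.q);
  };
  auto FMc = [&](const FAnchor& a, int c, int j, int l, int t) {
    return a.base + ((c * a.sj + (j - a.p)) * a.sl + (l - a.q)) * 3 + t;
  };
  auto FMMc = [&](const FAnchor& a, int c, int j, int l) {
    return a.mbase + (c * a.sj + (j - a.p)) * a.sl + (l - a.q);
  };
  auto Aq = [&](int qi) { return aq_base + qi; };

  // ---- external level ----
  g.edge(E(0, 0, 0));
  for (int r = 0; r < nm; ++r) {
    int j = am(r, 0), l = am(r, 1);
    for (int tp = 0; tp < 4; ++tp) {
      if (tp > 0) g.f(cf::trans_idx(est(tp), ST_M), 1);
      g.f(cf::matchem_idx(xs[j], ys[l]), 1);
      g.f(cf::F_EXT_UNPAIR, 2);
      g.edge(E(j, l, 1), E(j - 1, l - 1, tp), -1, -1, r);
    }
  }
  for (int j = 1; j <= N; ++j)
    for (int l = 0; l <= M; ++l)
      for (int tp : {0, 1, 3}) {
        if (tp > 0) g.f(cf::trans_idx(est(tp), ST_D), 1);
        g.f(cf::insertem_idx(xs[j]), 1);
        g.f(cf::F_EXT_UNPAIR, 1);
        g.edge(E(j, l, 3), E(j - 1, l, tp));
      }
  for (int j = 0; j <= N; ++j)
    for (int l = 1; l <= M; ++l)
      for (int tp : {0, 1, 2, 3}) {
        if (tp > 0) g.f(cf::trans_idx(est(tp), ST_I), 1);
        g.f(cf::insertem_idx(ys[l]), 1);
        g.f(cf::F_EXT_UNPAIR, 1);
        g.edge(E(j, l, 2), E(j, l - 1, tp));
      }
  for (int j = 0; j <= N; ++j)
    for (int l = 0; l <= M; ++l)
      for (int tp = 0; tp < 4; ++tp) {
        if (tp > 0) g.f(cf::trans_idx(est(tp), ST_M), 1);
        g.edge(EM(j, l), E(j, l, tp));
      }
  for (int qi = 0; qi < nq; ++qi) {
    g.f(cf::F_EXT_BRANCH, 2);
    g.edge(E(Q[qi].j, Q[qi].l, 1), EM(Q[qi].i - 1, Q[qi].k - 1), Aq(qi));
  }
  for (int tp = 0; tp < 4; ++tp) g.edge(final_node, E(N, M, tp));

  // ---- loop-level alignment stretches without branches (G) ----
  for (const GAnchor& a : GA) {
    g.edge(Gc(a, a.p, a.q, ST_M));
    for (int j = a.p; j <= a.extJ; ++j)
      for (int l = a.q; l <= a.extL; ++l) {
        if (j > a.p && l > a.q) {
          auto it = amid.find(key(j, l));
          if (it != amid.end()) {
            for (int tp : {ST_M, ST_I, ST_D}) {
              g.f(cf::trans_idx(tp, ST_M), 1);
              g.f(cf::matchem_idx(xs[j], ys[l]), 1);
              g.edge(Gc(a, j, l, ST_M), Gc(a, j - 1, l - 1, tp), -1, -1, it->second);
            }
          }
        }
        if (j > a.p)
          for (int tp : {ST_M, ST_D}) {
            g.f(cf::trans_idx(tp, ST_D), 1);
            g.f(cf::insertem_idx(xs[j]), 1);
            g.edge(Gc(a, j, l, ST_D), Gc(a, j - 1, l, tp));
          }
        if (l > a.q)
          for (int tp : {ST_M, ST_D, ST_I}) {
            g.f(cf::trans_idx(tp, ST_I), 1);
            g.f(cf::insertem_idx(ys[l]), 1);
            g.edge(Gc(a, j, l, ST_I), Gc(a, j, l - 1, tp));
          }
        for (int tp : {ST_M, ST_I, ST_D}) {
          g.f(cf::trans_idx(tp, ST_M), 1);
          g.edge(GMc(a, j, l), Gc(a, j, l, tp));
        }
      }
  }

  // ---- multibranch loop interiors (FM, branch count capped at 2 = ">=2") ----
  for (const FAnchor& a : FA) {
    if (a.base < 0) continue;
    g.edge(FMc(a, 0, a.p, a.q, ST_M));
    for (int c = 0; c < 3; ++c)
      for (int j = a.p; j <= a.extJ; ++j)
        for (int l = a.q; l <= a.extL; ++l) {
          if (j > a.p && l > a.q) {
            auto it = amid.find(key(j, l));
            if (it != amid.end()) {
              for (int tp : {ST_M, ST_I, ST_D}) {
                g.f(cf::trans_idx(tp, ST_M), 1);
                g.f(cf::matchem_idx(xs[j], ys[l]), 1);
                g.f(cf::F_MULTI_UNPAIR, 2);
                g.edge(FMc(a, c, j, l, ST_M), FMc(a, c, j - 1, l - 1, tp), -1, -1, it->second);
              }
            }
          }
          if (j > a.p)
            for (int tp : {ST_M, ST_D}) {
              g.f(cf::trans_idx(tp, ST_D), 1);
              g.f(cf::insertem_idx(xs[j]), 1);
              g.f(cf::F_MULTI_UNPAIR, 1);
              g.edge(FMc(a, c, j, l, ST_D), FMc(a, c, j - 1, l, tp));
            }
          if (l > a.q)
            for (int tp : {ST_M, ST_D, ST_I}) {
              g.f(cf::trans_idx(tp, ST_I), 1);
              g.f(cf::insertem_idx(ys[l]), 1);
              g.f(cf::F_MULTI_UNPAIR, 1);
              g.edge(FMc(a, c, j, l, ST_I), FMc(a, c, j, l - 1, tp));
            }
          for (int tp : {ST_M, ST_I, ST_D}) {
            g.f(cf::trans_idx(tp, ST_M), 1);
            g.edge(FMMc(a, c, j, l), FMc(a, c, j, l, tp));
          }
        }
    for (int qi = 0; qi < nq; ++qi) {
      const Quad& q2 = Q[qi];
      if (q2.i <= a.p || q2.k <= a.q || q2.j > a.extJ || q2.l > a.extL) continue;
      for (int c = 0; c < 3; ++c) {
        int cn = c + 1 > 2 ? 2 : c + 1;
        g.f(cf::F_MULTI_BRANCH, 2);
        g.edge(FMc(a, cn, q2.j, q2.l, ST_M), FMMc(a, c, q2.i - 1, q2.k - 1), Aq(qi));
      }
    }
  }

  // ---- matched base-pair closures (A states) ----
  for (int qi = 0; qi < nq; ++qi) {
    const Quad& q = Q[qi];
    const GAnchor& gl = GA[gmap[key(q.i, q.k)]];
    const FAnchor& fl = FA[fmap[key(q.i, q.k)]];
    auto pairfeats = [&]() {
      g.f(cf::bp_idx(xs[q.i], xs[q.j]), 1);
      g.f(cf::bp_idx(ys[q.k], ys[q.l]), 1);
      g.f(cf::matchem_idx(xs[q.i], ys[q.k]), 1);
      g.f(cf::matchem_idx(xs[q.j], ys[q.l]), 1);
    };
    if (q.j - q.i - 1 >= min_hairpin && q.l - q.k - 1 >= min_hairpin) {
      pairfeats();
      g.f(cf::hp_idx(q.j - q.i - 1), 1);
      g.f(cf::hp_idx(q.l - q.k - 1), 1);
      g.edge(Aq(qi), GMc(gl, q.j - 1, q.l - 1), -1, -1, q.amL, q.amR, qi);
    }
    for (int in2 : nested[qi]) {
      const Quad& q2 = Q[in2];
      const GAnchor& gr = GA[gmap[key(q2.j, q2.l)]];
      pairfeats();
      one_branch_feats(g, xs, q.i, q2.i, q2.j, q.j);
      one_branch_feats(g, ys, q.k, q2.k, q2.l, q.l);
      g.edge(Aq(qi), GMc(gl, q2.i - 1, q2.k - 1), Aq(in2),
             GMc(gr, q.j - 1, q.l - 1), q.amL, q.amR, qi);
    }
    if (fl.base >= 0) {
      pairfeats();
      g.f(cf::F_MULTI_BASE, 2);
      g.edge(Aq(qi), FMMc(fl, 2, q.j - 1, q.l - 1), -1, -1, q.amL, q.amR, qi);
    }
  }

  J.start_node = E(0, 0, 0);
  J.final_node = final_node;
}

// [[Rcpp::export]]
SEXP cpp_saf_build(IntegerVector x, IntegerVector y,
                   IntegerMatrix am, IntegerMatrix px, IntegerMatrix py,
                   int min_hairpin = 3) {
  std::vector<int> xs(x.size() + 1, 0), ys(y.size() + 1, 0);
  for (int i = 0; i < x.size(); ++i) xs[i + 1] = x[i];
  for (int i = 0; i < y.size(); ++i) ys[i + 1] = y[i];
  XPtr<JointGraph> ptr(new JointGraph(), true);
  build_joint(*ptr, xs, ys, am, px, py, min_hairpin);
  finalize_graph(ptr->g);
  return ptr;
}

// [[Rcpp::export]]
List cpp_saf_eval(SEXP graph, NumericVector theta,
                  bool want_counts = false, bool want_post = false,
                  int n_sample = 0) {
  if ((int)theta.size() != cf::NFEAT) stop("theta has wrong length");
  XPtr<JointGraph> J(graph);
  std::vector<double> th(theta.begin(), theta.end());
  Sweep s;
  run_inside(J->g, th, s);
  s.logz_in = s.ins[J->final_node];
  if (s.logz_in == NEG_INF) stop("no alignment candidate is realizable");

  List res = List::create(_["logz"] = s.logz_in);
  int nq = (int)J->quads.size();
  IntegerMatrix qm(nq, 6);
  for (int i = 0; i < nq; ++i) {
    qm(i, 0) = J->quads[i].i; qm(i, 1) = J->quads[i].j;
    qm(i, 2) = J->quads[i].k; qm(i, 3) = J->quads[i].l;
    qm(i, 4) = J->quads[i].pxrow + 1; qm(i, 5) = J->quads[i].pyrow + 1;
  }
  res["quads"] = qm;

  if (want_counts || want_post || n_sample > 0) {
    run_outside(J->g, s, J->final_node, J->start_node);
    res["logz_out"] = s.logz_out;
    std::vector<double> ec, pm, pq;
    std::vector<double>* ecp = nullptr; std::vector<double>* pmp = nullptr;
    std::vector<double>* pqp = nullptr;
    if (want_counts) { ec.assign(cf::NFEAT, 0.0); ecp = &ec; }
    if (want_post) {
      pm.assign(J->nmatch, 0.0); pq.assign(nq, 0.0);
      pmp = &pm; pqp = &pq;
    }
    if (ecp || pmp) accumulate(J->g, s, s.logz_in, ecp, pmp, pqp);
    if (want_counts) res["ecounts"] = NumericVector(ec.begin(), ec.end());
    if (want_post) {
      res["pm"] = NumericVector(pm.begin(), pm.end());
      res["pq"] = NumericVector(pq.begin(), pq.end());
    }
    if (n_sample > 0) {
      std::vector<int> inptr(J->g.nnodes + 1, 0), inedges(J->g.nedges());
      {
        std::vector<int> cnt(J->g.nnodes, 0);
        for (int e = 0; e < J->g.nedges(); ++e) cnt[J->g.head[e]]++;
        for (int n = 0; n < J->g.nnodes; ++n) inptr[n + 1] = inptr[n] + cnt[n];
        std::vector<int> fill(J->g.nnodes, 0);
        for (int e = 0; e < J->g.nedges(); ++e)
          inedges[inptr[J->g.head[e]] + fill[J->g.head[e]]++] = e;
      }
      GetRNGstate();
      List samples(n_sample);
      for (int si = 0; si < n_sample; ++si) {
        std::vector<int> ms, qs2;
        sample_one(J->g, s, inptr, inedges, J->final_node, ms, qs2);
        std::sort(ms.begin(), ms.end());
        std::sort(qs2.begin(), qs2.end());
        samples[si] = List::create(
          _["match"] = IntegerVector(ms.begin(), ms.end()),
          _["quad"] = IntegerVector(qs2.begin(), qs2.end()));
      }
      PutRNGstate();
      res["samples"] = samples;
    }
  }
  res["n_nodes"] = J->g.nnodes;
  res["n_edges"] = J->g.nedges();
  return res;
}

// ---------------------------------------------------------------------------
// single-sequence structure grammar (McCaskill-style, CONTRAfold features)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ss(IntegerVector x, IntegerMatrix pairs, NumericVector theta,
            int min_hairpin = 3, int max_loop = 30) {
  if ((int)theta.size() != cf::NFEAT) stop("theta has wrong length");
  int L = x.size();
  std::vector<int> xs(L + 1, 0);
  for (int i = 0; i < L; ++i) xs[i + 1] = x[i];
  int np = pairs.nrow();

  Graph g;
  g.nnodes = L + 1;                 // Es(0..L)
  int p_base = g.nnodes; g.nnodes += np;
  // FM anchors over distinct pair left-ends
  std::unordered_map<int, int> fmap;
  struct FA1 { int p, ext, base; };
  std::vector<FA1> FA;
  for (int r = 0; r < np; ++r) {
    int i = pairs(r, 0), j = pairs(r, 1);
    auto it = fmap.find(i);
    if (it == fmap.end()) { fmap[i] = (int)FA.size(); FA.push_back({i, j - 1, 0}); }
    else if (j - 1 > FA[it->second].ext) FA[it->second].ext = j - 1;
  }
  const int need1 = 2 * (min_hairpin + 2);
  for (auto& a : FA) {
    if (a.ext - a.p < need1) { a.base = -1; continue; }
    a.base = g.nnodes; g.nnodes += 3 * (a.ext - a.p + 1);
  }
  auto Es = [&](int j) { return j; };
  auto P = [&](int r) { return p_base + r; };
  auto FMc = [&](const FA1& a, int c, int j) { return a.base + c * (a.ext - a.p + 1) + (j - a.p); };

  g.edge(Es(0));
  for (int j = 1; j <= L; ++j) {
    g.f(cf::F_EXT_UNPAIR, 1);
    g.edge(Es(j), Es(j - 1));
  }
  for (int r = 0; r < np; ++r) {
    g.f(cf::F_EXT_BRANCH, 1);
    g.edge(Es(pairs(r, 1)), Es(pairs(r, 0) - 1), P(r));
  }
  for (const FA1& a : FA) {
    if (a.base < 0) continue;
    g.edge(FMc(a, 0, a.p));
    for (int c = 0; c < 3; ++c)
      for (int j = a.p + 1; j <= a.ext; ++j) {
        g.f(cf::F_MULTI_UNPAIR, 1);
        g.edge(FMc(a, c, j), FMc(a, c, j - 1));
      }
    for (int r = 0; r < np; ++r) {
      int i2 = pairs(r, 0), j2 = pairs(r, 1);
      if (i2 <= a.p || j2 > a.ext) continue;
      for (int c = 0; c < 3; ++c) {
        int cn = c + 1 > 2 ? 2 : c + 1;
        g.f(cf::F_MULTI_BRANCH, 1);
        g.edge(FMc(a, cn, j2), FMc(a, c, i2 - 1), P(r));
      }
    }
  }
  for (int r = 0; r < np; ++r) {
    int i = pairs(r, 0), j = pairs(r, 1);
    if (j - i - 1 >= min_hairpin) {
      g.f(cf::bp_idx(xs[i], xs[j]), 1);
      g.f(cf::hp_idx(j - i - 1), 1);
      g.edge(P(r), -1, -1, -1, -1, -1, r);
    }
    for (int r2 = 0; r2 < np; ++r2) {
      int i2 = pairs(r2, 0), j2 = pairs(r2, 1);
      if (i2 <= i || j2 >= j) continue;
      if ((i2 - i - 1) + (j - j2 - 1) > max_loop) continue;
      g.f(cf::bp_idx(xs[i], xs[j]), 1);
      one_branch_feats(g, xs, i, i2, j2, j);
      g.edge(P(r), P(r2), -1, -1, -1, -1, r);
    }
    auto it = fmap.find(i);
    if (it != fmap.end() && FA[it->second].base >= 0 &&
        j - 1 <= FA[it->second].ext && j - 1 >= i) {
      g.f(cf::bp_idx(xs[i], xs[j]), 1);
      g.f(cf::F_MULTI_BASE, 1);
      g.edge(P(r), FMc(FA[it->second], 2, j - 1), -1, -1, -1, -1, r);
    }
  }

  finalize_graph(g);
  std::vector<double> th(theta.begin(), theta.end());
  Sweep s;
  run_inside(g, th, s);
  s.logz_in = s.ins[Es(L)];
  run_outside(g, s, Es(L), Es(0));
  NumericVector pp(np);
  for (int r = 0; r < np; ++r) {
    double v = s.ins[P(r)] + s.out[P(r)];
    pp[r] = v == NEG_INF ? 0.0 : std::exp(v - s.logz_in);
  }
  return List::create(_["logz"] = s.logz_in, _["logz_out"] = s.logz_out,
                      _["pp"] = pp);
}

// [[Rcpp::export]]
List cpp_catalog() {
  const char* res = "ACGU";
  std::vector<std::string> d(cf::NFEAT), grp(cf::NFEAT);
  for (int a = 1; a <= 4; ++a)
    for (int b = a; b <= 4; ++b) {
      d[cf::matchem_idx(a, b)] = std::string("match_") + res[a - 1] + res[b - 1];
      grp[cf::matchem_idx(a, b)] = "match-emission";
    }
  for (int a = 1; a <= 4; ++a) {
    d[cf::insertem_idx(a)] = std::string("insert_") + res[a - 1];
    grp[cf::insertem_idx(a)] = "insert-emission";
  }
  const char* st = "MID";
  for (int p = 0; p < 3; ++p)
    for (int c = 0; c < 3; ++c) {
      d[cf::trans_idx(p, c)] = std::string("trans_") + st[p] + st[c];
      grp[cf::trans_idx(p, c)] = "align-transition";
    }
  for (int a = 1; a <= 4; ++a)
    for (int b = 1; b <= 4; ++b) {
      d[cf::bp_idx(a, b)] = std::string("bp_") + res[a - 1] + res[b - 1];
      grp[cf::bp_idx(a, b)] = "base-pair";
    }
  const char* canon[6] = {"AU", "CG", "GC", "GU", "UA", "UG"};
  for (int o = 0; o < 6; ++o)
    for (int i = 0; i < 6; ++i) {
      d[cf::OFF_STACK + o * 6 + i] = std::string("stack_") + canon[o] + "_" + canon[i];
      grp[cf::OFF_STACK + o * 6 + i] = "helix-stacking";
    }
  for (int n = 0; n <= 30; ++n) {
    d[cf::OFF_HP + n] = "hairpin_len_" + std::to_string(n);
    grp[cf::OFF_HP + n] = "hairpin-length";
    d[cf::OFF_BULGE + n] = "bulge_len_" + std::to_string(n);
    grp[cf::OFF_BULGE + n] = "bulge-length";
    d[cf::OFF_INT + n] = "internal_len_" + std::to_string(n);
    grp[cf::OFF_INT + n] = "internal-length";
    d[cf::OFF_ASYM + n] = "internal_asym_" + std::to_string(n);
    grp[cf::OFF_ASYM + n] = "internal-asymmetry";
  }
  d[cf::F_MULTI_BASE] = "multi_base"; d[cf::F_MULTI_BRANCH] = "multi_branch";
  d[cf::F_MULTI_UNPAIR] = "multi_unpaired";
  grp[cf::F_MULTI_BASE] = grp[cf::F_MULTI_BRANCH] = grp[cf::F_MULTI_UNPAIR] = "multibranch";
  d[cf::F_EXT_BRANCH] = "external_branch"; d[cf::F_EXT_UNPAIR] = "external_unpaired";
  grp[cf::F_EXT_BRANCH] = grp[cf::F_EXT_UNPAIR] = "external";
  return List::create(_["descriptor"] = wrap(d), _["group"] = wrap(grp));
}
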
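// Gamma-centroid pairwise/profile SAF decoding.
//
// Maximizes  sum_{(i,k) in M} (gm*pM - 1) + sum_{quads} (gp*(pPx+pPy) - 2)
// over pseudoknot-free, base-pairing-indel-free candidates.  States follow
// the two-level recursion: a_{ijkl} closes a matched base-pair quadruple and
// b_{ik}(j,l) extends the region opened at the match (i,k); b_{ik}(i,k) = 0
// and the answer is read at the virtual outermost anchor (0,0).  Only events
// passing the 1/gamma thresholds are materialized unless prune = FALSE.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct CQuad { int u, j, v, l, anchor; double alpha; };

// [[Rcpp::export]]
List cpp_centroid(NumericMatrix pm, NumericMatrix px, NumericMatrix py,
                  double gm, double gp, bool prune = true, int min_hairpin = 3) {
  int N = pm.nrow(), M = pm.ncol();
  double thm = 1.0 / gm, thp = 1.0 / gp;

  std::vector<char> em((N + 1) * (M + 1), 0);
  for (int i = 1; i <= N; ++i)
    for (int k = 1; k <= M; ++k)
      em[i * (M + 1) + k] = (!prune || pm(i - 1, k - 1) >= thm) ? 1 : 0;

  std::vector<std::pair<int, int>> Px, Py;
  for (int i = 1; i <= N; ++i)
    for (int j = i + min_hairpin + 1; j <= N; ++j)
      if (!prune || px(i - 1, j - 1) >= thp) Px.push_back({i, j});
  for (int k = 1; k <= M; ++k)
    for (int l = k + min_hairpin + 1; l <= M; ++l)
      if (!prune || py(k - 1, l - 1) >= thp) Py.push_back({k, l});

  // anchors: virtual (0,0) plus left ends of candidate quadruples
  std::unordered_map<long long, int> amap;
  auto key = [M](int i, int k) { return (long long)i * (M + 2) + k; };
  std::vector<std::pair<int, int>> anchors;
  amap[key(0, 0)] = 0;
  anchors.push_back({0, 0});
  // candidate quadruples are gated by the base-pair thresholds alone:
  // their endpoint matches enter through the quadruple bonus, so the
  // match threshold applies only to the unpaired-match recursion case
  // (this is what keeps the threshold pruning lossless)
  std::vector<CQuad> quads;
  std::vector<std::vector<int>> qend((N + 1) * (M + 1));
  for (auto& pxr : Px)
    for (auto& pyr : Py) {
      int u = pxr.first, j = pxr.second, v = pyr.first, l = pyr.second;
      int aid;
      auto it = amap.find(key(u, v));
      if (it == amap.end()) {
        aid = (int)anchors.size();
        amap[key(u, v)] = aid;
        anchors.push_back({u, v});
      } else aid = it->second;
      double alpha = gm * (pm(u - 1, v - 1) + pm(j - 1, l - 1)) +
                     gp * (px(u - 1, j - 1) + py(v - 1, l - 1)) - 4.0;
      qend[j * (M + 1) + l].push_back((int)quads.size());
      quads.push_back({u, j, v, l, aid, alpha});
    }

  int na = (int)anchors.size(), cells = (N + 1) * (M + 1);
  std::vector<double> b((size_t)na * cells, NEG_INF);
  std::vector<signed char> ch((size_t)na * cells, -1);   // 0 start,1 delx,2 dely,3 match,4 quad
  std::vector<int> chq((size_t)na * cells, -1);
  auto idx = [&](int a, int j, int l) { return (size_t)a * cells + j * (M + 1) + l; };

  for (int j = 0; j <= N; ++j)
    for (int l = 0; l <= M; ++l) {
      for (int a = 0; a < na; ++a) {
        int p = anchors[a].first, q = anchors[a].second;
        if (j < p || l < q) continue;
        if (j == p && l == q) { b[idx(a, j, l)] = 0.0; ch[idx(a, j, l)] = 0; continue; }
        double best = NEG_INF; signed char bc = -1; int bq = -1;
        if (j > p && b[idx(a, j - 1, l)] > best) { best = b[idx(a, j - 1, l)]; bc = 1; }
        if (l > q && b[idx(a, j, l - 1)] > best) { best = b[idx(a, j, l - 1)]; bc = 2; }
        if (j > p && l > q && em[j * (M + 1) + l]) {
          double v = b[idx(a, j - 1, l - 1)] + gm * pm(j - 1, l - 1) - 1.0;
          if (v > best) { best = v; bc = 3; }
        }
        for (int qi : qend[j * (M + 1) + l]) {
          const CQuad& q4 = quads[qi];
          if (q4.u <= p || q4.v <= q) continue;
          double v = b[idx(a, q4.u - 1, q4.v - 1)] +
                     b[idx(q4.anchor, j - 1, l - 1)] + q4.alpha;
          if (v > best) { best = v; bc = 4; bq = qi; }
        }
        b[idx(a, j, l)] = best; ch[idx(a, j, l)] = bc; chq[idx(a, j, l)] = bq;
      }
    }

  // traceback
  std::vector<std::array<int, 2>> mout;
  std::vector<std::array<int, 4>> qout;
  std::vector<std::array<int, 3>> stack;
  stack.push_back({0, N, M});
  while (!stack.empty()) {
    auto cur = stack.back(); stack.pop_back();
    int a = cur[0], j = cur[1], l = cur[2];
    signed char c = ch[idx(a, j, l)];
    if (c < 0) stop("internal error: centroid traceback hit an unreachable cell");
    if (c == 0) continue;
    if (c == 1) stack.push_back({a, j - 1, l});
    else if (c == 2) stack.push_back({a, j, l - 1});
    else if (c == 3) {
      mout.push_back({j, l});
      stack.push_back({a, j - 1, l - 1});
    } else {
      const CQuad& q4 = quads[chq[idx(a, j, l)]];
      qout.push_back({q4.u, q4.j, q4.v, q4.l});
      mout.push_back({q4.u, q4.v});
      mout.push_back({q4.j, q4.l});
      stack.push_back({q4.anchor, j - 1, l - 1});
      stack.push_back({a, q4.u - 1, q4.v - 1});
    }
  }
  std::sort(mout.begin(), mout.end());
  std::sort(qout.begin(), qout.end());
  IntegerMatrix mm((int)mout.size(), 2), qm((int)qout.size(), 4);
  for (int i = 0; i < (int)mout.size(); ++i) { mm(i, 0) = mout[i][0]; mm(i, 1) = mout[i][1]; }
  for (int i = 0; i < (int)qout.size(); ++i)
    for (int c2 = 0; c2 < 4; ++c2) qm(i, c2) = qout[i][c2];
  return List::create(_["match"] = mm, _["quad"] = qm,
                      _["score"] = b[idx(0, N, M)]);
}
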
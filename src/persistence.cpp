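// Core persistent-homology kernels: Z/2 boundary-matrix reduction for H1 of a
// flag filtration, minimum-volume bounding-chain search for persistent cycles,
// and a plain GF(2) rank routine used as an independent rank-nullity oracle.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <climits>
#include <cmath>
#include <functional>
using namespace Rcpp;

static std::vector<int> symdiff(const std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

// Reduce the (compressed) triangle boundary matrix of a flag filtration.
// Edges and triangles must already be in filtration order; indices are 1-based.
// tri_e gives, per triangle, the (1-based) indices of its three edges.
// Returns H1 pairs (birth edge, death triangle), the accumulated reduction
// chain per pair (an admissible bounding 2-chain, used as the initial upper
// bound for the optimal-cycle search), and unpaired creator edges.
// [[Rcpp::export]]
List ph_reduce_cpp(IntegerMatrix edge_v, IntegerMatrix tri_e, int n_vertices) {
  const int m = edge_v.nrow(), T = tri_e.nrow();
  // creator ("positive") edges: those whose endpoints are already connected
  std::vector<bool> positive(m + 1, false);
  UnionFind uf(n_vertices + 1);
  for (int e = 0; e < m; ++e)
    positive[e + 1] = !uf.unite(edge_v(e, 0), edge_v(e, 1));

  std::vector<int> owner(m + 1, -1);
  std::vector<std::vector<int> > cols, chains;
  std::vector<int> pair_edge, pair_tri;
  pair_edge.reserve(T); pair_tri.reserve(T);

  std::vector<int> col, chain;
  for (int t = 1; t <= T; ++t) {
    col.clear();
    for (int j = 0; j < 3; ++j) {
      int e = tri_e(t - 1, j);
      if (positive[e]) col.push_back(e);
    }
    std::sort(col.begin(), col.end());
    chain.assign(1, t);
    while (!col.empty()) {
      int low = col.back();
      int ow = owner[low];
      if (ow < 0) break;
      col = symdiff(col, cols[ow]);
      chain = symdiff(chain, chains[ow]);
    }
    if (col.empty()) continue;   // creates a 2-cycle; irrelevant for H1
    int low = col.back();
    owner[low] = (int) cols.size();
    cols.push_back(col);
    chains.push_back(chain);
    pair_edge.push_back(low);
    pair_tri.push_back(t);
  }

  std::vector<int> infinite;
  for (int e = 1; e <= m; ++e)
    if (positive[e] && owner[e] < 0) infinite.push_back(e);

  List rep(pair_edge.size());
  for (size_t i = 0; i < pair_edge.size(); ++i)
    rep[i] = wrap(chains[owner[pair_edge[i]]]);

  return List::create(_["birth_edge"] = wrap(pair_edge),
                      _["death_tri"] = wrap(pair_tri),
                      _["rep_chain"] = rep,
                      _["infinite_edges"] = wrap(infinite));
}

// ---- minimum-volume bounding chain ------------------------------------------

typedef std::vector<uint64_t> Bits;

static inline void bit_set(Bits& b, int i) { b[i >> 6] ^= (uint64_t(1) << (i & 63)); }
static inline bool bit_get(const Bits& b, int i) { return (b[i >> 6] >> (i & 63)) & 1; }
static inline int popcnt(const Bits& b) {
  int s = 0;
  for (size_t w = 0; w < b.size(); ++w) s += __builtin_popcountll(b[w]);
  return s;
}
static inline void bxor(Bits& a, const Bits& b) {
  for (size_t w = 0; w < a.size(); ++w) a[w] ^= b[w];
}

// Solve, for each finite H1 pair, the volume-minimisation problem: among
// 2-chains tau of triangles in the death-time complex (filtration prefix)
// that contain the death triangle and whose mod-2 boundary lies in the
// birth-time complex, find one with the fewest triangles.  Presolve =
// restriction to triangles carrying at least one constrained edge, connected
// component of the death triangle, and unit propagation; the residual GF(2)
// affine system is enumerated exactly over its kernel (Gray code) when the
// kernel dimension is at most cap_k.  status: 0 exact optimum found,
// 1 kernel too large (caller must fall back), 2 infeasible (never expected).
// [[Rcpp::export]]
List optimal_cycles_cpp(IntegerMatrix tri_e, IntegerVector birth_edge,
                        IntegerVector death_tri, List rep_chain,
                        int m_edges, int cap_k, double enum_budget = 8e6,
                        double ida_budget = 4e6) {
  const int T = tri_e.nrow(), P = birth_edge.size();
  // global edge -> triangle incidence
  std::vector<std::vector<int> > inc(m_edges + 1);
  for (int t = 1; t <= T; ++t)
    for (int j = 0; j < 3; ++j) inc[tri_e(t - 1, j)].push_back(t);

  std::vector<int> tri_stamp(T + 1, -1), edge_stamp(m_edges + 1, -1);
  std::vector<int> tri_local(T + 1, -1);
  List out(P);

  for (int p = 0; p < P; ++p) {
    const int be = birth_edge[p], dt = death_tri[p], stamp = p;
    // BFS over the constrained-edge incidence graph from the death triangle
    std::vector<int> cand;               // global triangle ids in component
    std::vector<int> cedges;             // constrained edge ids touched
    std::vector<int> queue1;
    queue1.push_back(dt);
    tri_stamp[dt] = stamp;
    while (!queue1.empty()) {
      int t = queue1.back(); queue1.pop_back();
      cand.push_back(t);
      for (int j = 0; j < 3; ++j) {
        int e = tri_e(t - 1, j);
        if (e <= be) continue;           // unconstrained: edge in birth complex
        if (edge_stamp[e] != stamp) { edge_stamp[e] = stamp; cedges.push_back(e); }
        const std::vector<int>& ts = inc[e];
        for (size_t q = 0; q < ts.size(); ++q) {
          int t2 = ts[q];
          if (t2 > dt || tri_stamp[t2] == stamp) continue;
          tri_stamp[t2] = stamp;
          queue1.push_back(t2);
        }
      }
    }
    const int nv = (int) cand.size();
    std::sort(cand.begin(), cand.end());
    for (int i = 0; i < nv; ++i) tri_local[cand[i]] = i;
    std::sort(cedges.begin(), cedges.end());
    const int nr = (int) cedges.size();
    std::vector<int> edge_local(nr);
    std::vector<std::vector<int> > rows(nr);  // row -> local var ids
    for (int i = 0; i < nr; ++i) edge_stamp[cedges[i]] = -1; // reuse as map via lookup below
    // local row index lookup
    std::vector<int> row_of(m_edges + 1, -1);
    for (int i = 0; i < nr; ++i) row_of[cedges[i]] = i;
    for (int i = 0; i < nv; ++i) {
      int t = cand[i];
      for (int j = 0; j < 3; ++j) {
        int r = row_of[tri_e(t - 1, j)];
        if (r >= 0) rows[r].push_back(i);
      }
    }

    // force the death triangle in, then unit-propagate
    std::vector<int> state(nv, -1);      // -1 free, 0 forced out, 1 forced in
    std::vector<char> target(nr, 0);
    std::vector<int> deg(nr, 0);
    for (int r = 0; r < nr; ++r) deg[r] = (int) rows[r].size();
    const int dloc = tri_local[dt];
    bool infeasible = false;
    std::vector<int> force_q;
    force_q.push_back(dloc);
    std::vector<char> force_val;
    force_val.push_back(1);
    while (!force_q.empty()) {
      int v = force_q.back(); force_q.pop_back();
      char val = force_val.back(); force_val.pop_back();
      if (state[v] != -1) { if (state[v] != val) { infeasible = true; break; } continue; }
      state[v] = val;
      int t = cand[v];
      for (int j = 0; j < 3; ++j) {
        int r = row_of[tri_e(t - 1, j)];
        if (r < 0) continue;
        if (val) target[r] ^= 1;
        if (--deg[r] == 1) {
          // find the last free var in this row and force it
          int vfree = -1;
          for (size_t q = 0; q < rows[r].size(); ++q)
            if (state[rows[r][q]] == -1) { vfree = rows[r][q]; break; }
          if (vfree >= 0) { force_q.push_back(vfree); force_val.push_back(target[r]); }
        } else if (deg[r] == 0 && target[r]) { infeasible = true; }
      }
      if (infeasible) break;
    }
    // recount degrees cleanly (propagation above may force several at once)
    if (!infeasible) {
      for (int r = 0; r < nr; ++r) {
        int d2 = 0; char tg = 0;
        for (size_t q = 0; q < rows[r].size(); ++q) {
          int v = rows[r][q];
          if (state[v] == -1) ++d2; else if (state[v] == 1) tg ^= 1;
        }
        if (d2 == 0 && tg) { infeasible = true; break; }
      }
    }
    if (infeasible) {
      out[p] = List::create(_["status"] = 2);
      for (int i = 0; i < nv; ++i) tri_local[cand[i]] = -1;
      continue;
    }

    // remaining free variables
    std::vector<int> freev;
    for (int v = 0; v < nv; ++v) if (state[v] == -1) freev.push_back(v);
    const int nfv = (int) freev.size();
    std::vector<int> fidx(nv, -1);
    for (int i = 0; i < nfv; ++i) fidx[freev[i]] = i;
    const int words = std::max(1, (nfv + 63) >> 6);

    // Gaussian elimination on rows restricted to free vars
    std::vector<Bits> mat;
    std::vector<char> rhs;
    for (int r = 0; r < nr; ++r) {
      Bits row(words, 0);
      int cnt = 0; char tg = 0;
      for (size_t q = 0; q < rows[r].size(); ++q) {
        int v = rows[r][q];
        if (state[v] == -1) { bit_set(row, fidx[v]); ++cnt; }
        else if (state[v] == 1) tg ^= 1;
      }
      if (cnt == 0) continue;
      mat.push_back(row);
      rhs.push_back(tg);
    }
    std::vector<int> pivot_col;
    int rank = 0;
    for (int c = 0; c < nfv && rank < (int) mat.size(); ++c) {
      int pr = -1;
      for (int r = rank; r < (int) mat.size(); ++r)
        if (bit_get(mat[r], c)) { pr = r; break; }
      if (pr < 0) continue;
      std::swap(mat[rank], mat[pr]);
      std::swap(rhs[rank], rhs[pr]);
      for (int r = 0; r < (int) mat.size(); ++r) {
        if (r != rank && bit_get(mat[r], c)) { bxor(mat[r], mat[rank]); rhs[r] ^= rhs[rank]; }
      }
      pivot_col.push_back(c);
      ++rank;
    }
    for (int r = rank; r < (int) mat.size(); ++r)
      if (rhs[r]) { infeasible = true; break; }
    if (infeasible) {
      out[p] = List::create(_["status"] = 2);
      for (int i = 0; i < nv; ++i) tri_local[cand[i]] = -1;
      continue;
    }
    std::vector<bool> is_pivot(nfv, false);
    for (int i = 0; i < rank; ++i) is_pivot[pivot_col[i]] = true;
    std::vector<int> freecols;
    for (int c = 0; c < nfv; ++c) if (!is_pivot[c]) freecols.push_back(c);
    const int k = (int) freecols.size();

    const double enum_cost = (k >= 60) ? 1e30 : std::ldexp((double) words, k);
    if (k > cap_k || enum_cost > enum_budget) {
      // Exact iterative-deepening search over the propagated system: grow a
      // chain from the forced set, always covering a currently odd-parity
      // constrained edge; admissible bound = ceil(violated / 3) since a
      // triangle flips at most three constrained edges.
      std::vector<std::vector<int> > rowsF;       // rows -> free var ids
      std::vector<char> parF;                     // current parity (1 = violated)
      std::vector<std::vector<int> > var_rows(nv);
      for (int r = 0; r < nr; ++r) {
        std::vector<int> vs;
        char tg = 0;
        for (size_t q = 0; q < rows[r].size(); ++q) {
          int v = rows[r][q];
          if (state[v] == -1) vs.push_back(v);
          else if (state[v] == 1) tg ^= 1;
        }
        if (vs.empty()) continue;
        int rid = (int) rowsF.size();
        for (size_t q = 0; q < vs.size(); ++q) var_rows[vs[q]].push_back(rid);
        rowsF.push_back(vs);
        parF.push_back(tg);
      }
      int viol = 0;
      for (size_t r = 0; r < parF.size(); ++r) viol += parF[r];
      std::vector<char> used(nv, 0);
      std::vector<int> chosen;
      long long budget = (long long) ida_budget;
      bool found = false, overran = false;

      std::function<bool(int)> dfs = [&](int depth_left) -> bool {
        if (viol == 0) return true;
        if ((viol + 2) / 3 > depth_left) return false;
        if (--budget < 0) { overran = true; return false; }
        // fail-first: violated row with fewest unused covering triangles
        int rbest = -1, cbest = INT_MAX;
        for (size_t r = 0; r < rowsF.size(); ++r) {
          if (!parF[r]) continue;
          int cnt = 0;
          for (size_t q = 0; q < rowsF[r].size(); ++q)
            if (!used[rowsF[r][q]]) ++cnt;
          if (cnt < cbest) { cbest = cnt; rbest = (int) r; if (cnt <= 1) break; }
        }
        if (cbest == 0) return false;
        std::vector<int> opts;
        for (size_t q = 0; q < rowsF[rbest].size(); ++q)
          if (!used[rowsF[rbest][q]]) opts.push_back(rowsF[rbest][q]);
        for (size_t o = 0; o < opts.size() && !overran; ++o) {
          int v = opts[o];
          used[v] = 1;
          chosen.push_back(v);
          for (size_t q = 0; q < var_rows[v].size(); ++q) {
            int r = var_rows[v][q];
            parF[r] ^= 1;
            viol += parF[r] ? 1 : -1;
          }
          if (dfs(depth_left - 1)) return true;
          for (size_t q = 0; q < var_rows[v].size(); ++q) {
            int r = var_rows[v][q];
            parF[r] ^= 1;
            viol += parF[r] ? 1 : -1;
          }
          chosen.pop_back();
          used[v] = 0;
        }
        return false;
      };

      for (int limit = (viol + 2) / 3; limit <= nv && !found && !overran; ++limit)
        found = dfs(limit);

      if (!found) {
        out[p] = List::create(_["status"] = 1, _["k"] = k);
        for (int i = 0; i < nv; ++i) tri_local[cand[i]] = -1;
        continue;
      }
      std::vector<int> tris;
      for (int v = 0; v < nv; ++v)
        if (state[v] == 1 || used[v]) tris.push_back(cand[v]);
      std::vector<char> par(m_edges + 1, 0);
      std::vector<int> touched;
      for (size_t q = 0; q < tris.size(); ++q)
        for (int j = 0; j < 3; ++j) {
          int e = tri_e(tris[q] - 1, j);
          touched.push_back(e);
          par[e] ^= 1;
        }
      std::sort(touched.begin(), touched.end());
      touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
      std::vector<int> cyc;
      for (size_t q = 0; q < touched.size(); ++q)
        if (par[touched[q]]) cyc.push_back(touched[q]);
      out[p] = List::create(_["status"] = 0, _["tris"] = wrap(tris),
                            _["cycle_edges"] = wrap(cyc),
                            _["volume"] = (int) tris.size(), _["k"] = k);
      for (int i = 0; i < nv; ++i) tri_local[cand[i]] = -1;
      continue;
    }

    // particular solution (free cols = 0) and kernel basis over free vars
    Bits x0(words, 0);
    for (int i = 0; i < rank; ++i) if (rhs[i]) bit_set(x0, pivot_col[i]);
    std::vector<Bits> kern(k, Bits(words, 0));
    for (int j = 0; j < k; ++j) {
      bit_set(kern[j], freecols[j]);
      for (int i = 0; i < rank; ++i)
        if (bit_get(mat[i], freecols[j])) bit_set(kern[j], pivot_col[i]);
    }

    Bits cur = x0, best = x0;
    int bw = popcnt(cur);
    uint64_t niter = (k >= 1) ? ((uint64_t(1) << k) - 1) : 0;
    for (uint64_t i = 1; i <= niter; ++i) {
      int j = __builtin_ctzll(i);
      bxor(cur, kern[j]);
      int w = popcnt(cur);
      if (w < bw) { bw = w; best = cur; }
    }

    // assemble the chain: forced-in vars + chosen free-var solution
    std::vector<int> tris;
    for (int v = 0; v < nv; ++v) {
      bool in = (state[v] == 1) || (state[v] == -1 && bit_get(best, fidx[v]));
      if (in) tris.push_back(cand[v]);
    }
    // boundary of the chain
    std::vector<int> edge_cnt_ids;
    std::vector<char> par(m_edges + 1, 0);
    for (size_t q = 0; q < tris.size(); ++q) {
      int t = tris[q];
      for (int j = 0; j < 3; ++j) {
        int e = tri_e(t - 1, j);
        edge_cnt_ids.push_back(e);
        par[e] ^= 1;
      }
    }
    std::sort(edge_cnt_ids.begin(), edge_cnt_ids.end());
    edge_cnt_ids.erase(std::unique(edge_cnt_ids.begin(), edge_cnt_ids.end()),
                       edge_cnt_ids.end());
    std::vector<int> cyc;
    for (size_t q = 0; q < edge_cnt_ids.size(); ++q)
      if (par[edge_cnt_ids[q]]) cyc.push_back(edge_cnt_ids[q]);

    out[p] = List::create(_["status"] = 0, _["tris"] = wrap(tris),
                          _["cycle_edges"] = wrap(cyc),
                          _["volume"] = (int) tris.size(), _["k"] = k);
    for (int i = 0; i < nv; ++i) tri_local[cand[i]] = -1;
  }
  return out;
}

// Rank of a 0/1 matrix over GF(2), given as 1-based triplet indices.
// [[Rcpp::export]]
int gf2_rank_cpp(IntegerVector ri, IntegerVector ci, int nrow, int ncol) {
  if (nrow == 0 || ncol == 0 || ri.size() == 0) return 0;
  const int words = (ncol + 63) >> 6;
  std::vector<Bits> rows(nrow, Bits(words, 0));
  for (int i = 0; i < ri.size(); ++i) bit_set(rows[ri[i] - 1], ci[i] - 1);
  int rank = 0;
  for (int c = 0; c < ncol && rank < nrow; ++c) {
    int pr = -1;
    for (int r = rank; r < nrow; ++r)
      if (bit_get(rows[r], c)) { pr = r; break; }
    if (pr < 0) continue;
    std::swap(rows[rank], rows[pr]);
    for (int r = rank + 1; r < nrow; ++r)
      if (bit_get(rows[r], c)) bxor(rows[r], rows[rank]);
    ++rank;
  }
  return rank;
}
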
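#include <Rcpp.h>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Greedy local search for sign-consistent biclusters of a ternary matrix.
// The sign of each included comparison is always the majority nonzero sign
// over the current gene set (ties +1), so the additive score
//   sum_c [ a * n_match(c) - d * n_mismatch(c) - b * n_zero(c) ]
// is a function of the (gene set, comparison set) pair alone. Moves are the
// single best-scoring addition or removal of one gene or one comparison;
// ties are broken by scan order (gene additions, gene removals, comparison
// additions, comparison removals, each in ascending index), which makes the
// search fully deterministic.

static inline double colscore(int np, int nm, int n0, double a, double b, double d) {
  int match = np >= nm ? np : nm;
  int mis = np >= nm ? nm : np;
  return a * match - d * mis - b * n0;
}

struct State {
  int n, m;
  const int *x;                 // column-major n x m, entries -1/0/1
  double a, b, d;
  std::vector<char> inG, inC;
  std::vector<int> np, nm, n0;  // per-column counts over current genes
  int gsize = 0, csize = 0;
  double score = 0.0;

  State(const IntegerMatrix &X, double a_, double b_, double d_)
      : n(X.nrow()), m(X.ncol()), x(X.begin()), a(a_), b(b_), d(d_),
        inG(n, 0), inC(m, 0), np(m, 0), nm(m, 0), n0(m, 0) {}

  inline int val(int g, int c) const { return x[(size_t)c * n + g]; }

  double cur_colscore(int c) const { return colscore(np[c], nm[c], n0[c], a, b, d); }

  void add_gene(int g) {
    for (int c = 0; c < m; ++c) {
      int v = val(g, c);
      if (v > 0) ++np[c]; else if (v < 0) ++nm[c]; else ++n0[c];
    }
    inG[g] = 1; ++gsize;
  }
  void remove_gene(int g) {
    for (int c = 0; c < m; ++c) {
      int v = val(g, c);
      if (v > 0) --np[c]; else if (v < 0) --nm[c]; else --n0[c];
    }
    inG[g] = 0; --gsize;
  }

  // delta of adding (sign=+1) / removing (sign=-1) gene g, given the active
  // columns `ac` and their cached current column scores `cs`
  double gene_delta(int g, int sign, const std::vector<int> &ac,
                    const std::vector<double> &cs) const {
    double delta = 0.0;
    for (size_t k = 0; k < ac.size(); ++k) {
      int c = ac[k];
      int p = np[c], q = nm[c], z = n0[c];
      int v = val(g, c);
      if (v > 0) p += sign; else if (v < 0) q += sign; else z += sign;
      delta += colscore(p, q, z, a, b, d) - cs[k];
    }
    return delta;
  }

  double total_score() const {
    double s = 0.0;
    for (int c = 0; c < m; ++c) if (inC[c]) s += cur_colscore(c);
    return s;
  }
};

// one strictly-improving greedy pass; G/C seeds are modified in place
static void greedy(State &st, int min_genes, int min_comps) {
  int guard = 50 * (st.n + st.m) + 1000;
  while (guard-- > 0) {
    double best = 0.0;
    int kind = -1, idx = -1;  // 0 add gene, 1 rm gene, 2 add comp, 3 rm comp
    std::vector<int> ac;
    std::vector<double> cs;
    ac.reserve(st.csize); cs.reserve(st.csize);
    for (int c = 0; c < st.m; ++c)
      if (st.inC[c]) { ac.push_back(c); cs.push_back(st.cur_colscore(c)); }
    for (int g = 0; g < st.n; ++g) {
      if (st.inG[g]) continue;
      double d = st.gene_delta(g, +1, ac, cs);
      if (d > best + 1e-9) { best = d; kind = 0; idx = g; }
    }
    int min_g = min_genes > 1 ? min_genes : 1;
    if (st.gsize > min_g) {
      for (int g = 0; g < st.n; ++g) {
        if (!st.inG[g]) continue;
        double d = st.gene_delta(g, -1, ac, cs);
        if (d > best + 1e-9) { best = d; kind = 1; idx = g; }
      }
    }
    int min_c = min_comps > 1 ? min_comps : 1;
    for (int c = 0; c < st.m; ++c) {
      if (st.inC[c]) {
        if (st.csize > min_c) {
          double d = -st.cur_colscore(c);
          if (d > best + 1e-9) { best = d; kind = 3; idx = c; }
        }
      } else {
        double d = st.cur_colscore(c);
        if (d > best + 1e-9) { best = d; kind = 2; idx = c; }
      }
    }
    if (kind < 0) break;
    switch (kind) {
      case 0: st.add_gene(idx); break;
      case 1: st.remove_gene(idx); break;
      case 2: st.inC[idx] = 1; ++st.csize; break;
      case 3: st.inC[idx] = 0; --st.csize; break;
    }
  }
  st.score = st.total_score();
}

static void apply_move(State &st, int kind, int idx) {
  switch (kind) {
    case 0: st.add_gene(idx); break;
    case 1: st.remove_gene(idx); break;
    case 2: st.inC[idx] = 1; ++st.csize; break;
    case 3: st.inC[idx] = 0; --st.csize; break;
  }
}

static std::string state_key(const State &st) {
  std::string key;
  key.reserve(st.n + st.m + 1);
  for (int g = 0; g < st.n; ++g) key.push_back(st.inG[g] ? '1' : '0');
  key.push_back('|');
  for (int c = 0; c < st.m; ++c) key.push_back(st.inC[c] ? '1' : '0');
  return key;
}

// score-neutral single moves from a greedy-converged state, in scan order
static std::vector<std::pair<int, int>> plateau_moves(const State &st,
                                                      int min_genes,
                                                      int min_comps,
                                                      int cap) {
  std::vector<std::pair<int, int>> out;
  std::vector<int> ac;
  std::vector<double> cs;
  for (int c = 0; c < st.m; ++c)
    if (st.inC[c]) { ac.push_back(c); cs.push_back(st.cur_colscore(c)); }
  int min_g = min_genes > 1 ? min_genes : 1;
  int min_c = min_comps > 1 ? min_comps : 1;
  for (int g = 0; g < st.n && (int)out.size() < cap; ++g) {
    int sg = st.inG[g] ? -1 : +1;
    if (sg < 0 && st.gsize <= min_g) continue;
    double d = st.gene_delta(g, sg, ac, cs);
    if (d > -1e-9 && d < 1e-9) out.push_back({sg > 0 ? 0 : 1, g});
  }
  for (int c = 0; c < st.m && (int)out.size() < cap; ++c) {
    if (st.inC[c] && st.csize <= min_c) continue;
    double d = st.inC[c] ? -st.cur_colscore(c) : st.cur_colscore(c);
    if (d > -1e-9 && d < 1e-9) out.push_back({st.inC[c] ? 3 : 2, c});
  }
  return out;
}

// Depth-first exploration of score-neutral plateau chains from a local
// optimum: apply a neutral move, descend greedily, and either accept a
// strict improvement or recurse on the equal-score state. Bounded by depth,
// a node budget and a visited set, so it is deterministic and terminates.
static bool explore_plateaus(const State &opt, int min_genes, int min_comps,
                             int depth, int &budget, State &out,
                             std::set<std::string> &visited) {
  if (depth == 0 || budget <= 0) return false;
  auto moves = plateau_moves(opt, min_genes, min_comps, 32);
  for (auto &mv : moves) {
    if (--budget <= 0) return false;
    State trial = opt;
    apply_move(trial, mv.first, mv.second);
    greedy(trial, min_genes, min_comps);
    if (!visited.insert(state_key(trial)).second) continue;
    if (trial.score > opt.score + 1e-9) { out = trial; return true; }
    if (explore_plateaus(trial, min_genes, min_comps, depth - 1, budget, out,
                         visited))
      return true;
  }
  return false;
}

// greedy descent with plateau escape, repeated until no chain of at most
// `depth` neutral moves leads to a better local optimum
static void greedy_with_plateaus(State &st, int min_genes, int min_comps) {
  greedy(st, min_genes, min_comps);
  for (int rounds = 0; rounds < 200; ++rounds) {
    std::set<std::string> visited;
    visited.insert(state_key(st));
    int budget = 256;
    State better = st;
    if (!explore_plateaus(st, min_genes, min_comps, 6, budget, better, visited))
      break;
    st = better;
  }
}

// [[Rcpp::export(name = ".bicluster_search_cpp")]]
List bicluster_search_cpp(IntegerMatrix X, double a, double b, double d,
                          int min_genes, int min_comps, double theta) {
  int n = X.nrow(), m = X.ncol();
  std::set<std::string> seen;
  List out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // seed: comparisons where both genes carry the same nonzero call
      std::vector<int> cols;
      for (int c = 0; c < m; ++c) {
        int vi = X[(size_t)c * n + i];
        if (vi != 0 && vi == X[(size_t)c * n + j]) cols.push_back(c);
      }
      if ((int)cols.size() < (min_comps > 1 ? min_comps : 1)) continue;

      State st(X, a, b, d);
      st.add_gene(i); st.add_gene(j);
      for (int c : cols) { st.inC[c] = 1; ++st.csize; }
      greedy_with_plateaus(st, min_genes, min_comps);

      if (st.score < theta || st.gsize < min_genes || st.csize < min_comps)
        continue;
      std::string key;
      key.reserve(n + m + 1);
      for (int g = 0; g < n; ++g) key.push_back(st.inG[g] ? '1' : '0');
      key.push_back('|');
      for (int c = 0; c < m; ++c) key.push_back(st.inC[c] ? '1' : '0');
      if (!seen.insert(key).second) continue;

      IntegerVector genes, comps, signs;
      for (int g = 0; g < n; ++g) if (st.inG[g]) genes.push_back(g + 1);
      for (int c = 0; c < m; ++c) if (st.inC[c]) {
        comps.push_back(c + 1);
        signs.push_back(st.np[c] >= st.nm[c] ? 1 : -1);
      }
      out.push_back(List::create(_["genes"] = genes, _["comparisons"] = comps,
                                 _["signs"] = signs, _["score"] = st.score));
    }
  }
  return out;
}
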
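#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Depth-limited regression trees fitted to gradient targets by exhaustive
// variance-reduction split search. Categorical splits use the target-mean
// level ordering, which is optimal for squared error; levels are coded
// 1..31 and a split stores a bitmask of levels routed left. Ties on gain
// are broken by the caller-supplied variable priority (the fitter passes
// alphabetical name rank, so results do not depend on column order), then
// by the lowest threshold (the scan accepts strictly better gains only,
// in ascending order).

struct Node {
  int var;            // -1 for leaf
  double split;       // threshold (midpoint between adjacent values)
  unsigned int lmask; // categorical: levels routed left
  unsigned int smask; // categorical: levels seen in this node at training
  int left, right;
  double improve;     // squared-error improvement of this split
  int n;              // bag rows reaching the node
  int n_left, n_right;
  double value;       // terminal value (set by the caller via set_values)
};

struct SplitChoice {
  int var = -1;
  double split = 0.0;
  unsigned int lmask = 0, smask = 0;
  double gain = 0.0;
};

static SplitChoice find_split(const NumericMatrix& X, const LogicalVector& is_cat,
                              const NumericVector& z, const std::vector<int>& rows,
                              int min_obs, const IntegerVector& pref) {
  SplitChoice best;
  const int n = (int)rows.size();
  if (n < 2 * min_obs) return best;
  double S = 0.0;
  for (int r : rows) S += z[r];
  const double base = S * S / n;
  const int p = X.ncol();

  std::vector<std::pair<double,double>> xz;
  for (int j = 0; j < p; ++j) {
    if (!is_cat[j]) {
      xz.clear();
      xz.reserve(n);
      for (int r : rows) xz.emplace_back(X(r, j), z[r]);
      std::sort(xz.begin(), xz.end(),
                [](const std::pair<double,double>& a, const std::pair<double,double>& b) {
                  return a.first < b.first;
                });
      double SL = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        SL += xz[k].second;
        const int nL = k + 1, nR = n - nL;
        if (xz[k].first >= xz[k + 1].first) continue; // only between distinct values
        if (nL < min_obs || nR < min_obs) continue;
        const double SR = S - SL;
        const double gain = SL * SL / nL + SR * SR / nR - base;
        if (gain > best.gain ||
            (best.var >= 0 && gain == best.gain && pref[j] < pref[best.var])) {
          best.var = j;
          best.split = (xz[k].first + xz[k + 1].first) / 2.0;
          best.lmask = 0; best.smask = 0;
          best.gain = gain;
        }
      }
    } else {
      double sum[32]; int cnt[32];
      std::fill(sum, sum + 32, 0.0);
      std::fill(cnt, cnt + 32, 0);
      unsigned int seen = 0;
      for (int r : rows) {
        const int code = (int)X(r, j) - 1; // levels coded 1..31
        if (code < 0 || code > 31) stop("categorical code out of range 1..31");
        sum[code] += z[r];
        cnt[code] += 1;
        seen |= (1u << code);
      }
      std::vector<int> lev;
      for (int c = 0; c < 32; ++c) if (cnt[c] > 0) lev.push_back(c);
      if (lev.size() < 2) continue;
      std::sort(lev.begin(), lev.end(), [&](int a, int b) {
        const double ma = sum[a] / cnt[a], mb = sum[b] / cnt[b];
        if (ma != mb) return ma < mb;
        return a < b;
      });
      double SL = 0.0; int nL = 0; unsigned int mask = 0;
      for (size_t k = 0; k + 1 < lev.size(); ++k) {
        SL += sum[lev[k]];
        nL += cnt[lev[k]];
        mask |= (1u << lev[k]);
        const int nR = n - nL;
        if (nL < min_obs || nR < min_obs) continue;
        const double SR = S - SL;
        const double gain = SL * SL / nL + SR * SR / nR - base;
        if (gain > best.gain ||
            (best.var >= 0 && gain == best.gain && pref[j] < pref[best.var])) {
          best.var = j;
          best.split = NA_REAL;
          best.lmask = mask;
          best.smask = seen;
          best.gain = gain;
        }
      }
    }
  }
  return best;
}

static int grow_node(std::vector<Node>& nodes,
                     std::vector<int>& leaf_of_row, // indexed by bag position
                     const std::vector<int>& rows, const std::vector<int>& pos,
                     const NumericMatrix& X, const LogicalVector& is_cat,
                     const NumericVector& z, int depth, int max_depth, int min_obs,
                     const IntegerVector& pref) {
  const int id = (int)nodes.size();
  nodes.push_back(Node{-1, NA_REAL, 0u, 0u, -1, -1, 0.0, (int)rows.size(), 0, 0, 0.0});
  SplitChoice sp;
  if (depth < max_depth) sp = find_split(X, is_cat, z, rows, min_obs, pref);
  if (sp.var < 0 || sp.gain <= 0.0) {
    for (int q : pos) leaf_of_row[q] = id;
    return id;
  }
  std::vector<int> lr, rr, lp, rp;
  for (size_t k = 0; k < rows.size(); ++k) {
    const int r = rows[k];
    bool goes_left;
    if (is_cat[sp.var]) {
      const int code = (int)X(r, sp.var) - 1;
      goes_left = (sp.lmask >> code) & 1u;
    } else {
      goes_left = X(r, sp.var) < sp.split;
    }
    if (goes_left) { lr.push_back(r); lp.push_back(pos[k]); }
    else           { rr.push_back(r); rp.push_back(pos[k]); }
  }
  nodes[id].var = sp.var;
  nodes[id].split = sp.split;
  nodes[id].lmask = sp.lmask;
  nodes[id].smask = sp.smask;
  nodes[id].improve = sp.gain;
  nodes[id].n_left = (int)lr.size();
  nodes[id].n_right = (int)rr.size();
  const int li = grow_node(nodes, leaf_of_row, lr, lp, X, is_cat, z,
                           depth + 1, max_depth, min_obs, pref);
  const int ri = grow_node(nodes, leaf_of_row, rr, rp, X, is_cat, z,
                           depth + 1, max_depth, min_obs, pref);
  nodes[id].left = li;
  nodes[id].right = ri;
  return id;
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, LogicalVector is_cat, NumericVector z,
                   IntegerVector bag_rows, int max_depth, int min_obs,
                   IntegerVector pref) {
  std::vector<int> rows(bag_rows.begin(), bag_rows.end()); // 0-based
  std::vector<int> pos(rows.size());
  for (size_t k = 0; k < rows.size(); ++k) pos[k] = (int)k;
  std::vector<int> leaf_of_row(rows.size(), -1);
  std::vector<Node> nodes;
  grow_node(nodes, leaf_of_row, rows, pos, X, is_cat, z, 0, max_depth, min_obs, pref);

  const int m = (int)nodes.size();
  IntegerVector var(m), left(m), right(m), nn(m), nl(m), nr(m);
  NumericVector split(m), improve(m), lmask(m), smask(m), value(m);
  for (int i = 0; i < m; ++i) {
    var[i] = nodes[i].var; split[i] = nodes[i].split;
    lmask[i] = (double)nodes[i].lmask; smask[i] = (double)nodes[i].smask;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    improve[i] = nodes[i].improve; nn[i] = nodes[i].n;
    nl[i] = nodes[i].n_left; nr[i] = nodes[i].n_right;
    value[i] = 0.0;
  }
  return List::create(_["var"] = var, _["split"] = split,
                      _["lmask"] = lmask, _["smask"] = smask,
                      _["left"] = left, _["right"] = right,
                      _["improve"] = improve, _["n"] = nn,
                      _["n_left"] = nl, _["n_right"] = nr,
                      _["value"] = value,
                      _["leaf_of_bag"] = IntegerVector(leaf_of_row.begin(),
                                                       leaf_of_row.end()));
}

static int route_row(const IntegerVector& var, const NumericVector& split,
                     const NumericVector& lmask, const NumericVector& smask,
                     const IntegerVector& left, const IntegerVector& right,
                     const IntegerVector& nl, const IntegerVector& nr,
                     const LogicalVector& is_cat, const NumericMatrix& X, int row) {
  int i = 0;
  while (var[i] >= 0) {
    const int j = var[i];
    bool goes_left;
    const double x = X(row, j);
    if (is_cat[j]) {
      const int code = (int)x - 1;
      const unsigned int sm = (unsigned int)smask[i];
      if (code < 0 || code > 31 || !((sm >> code) & 1u) || ISNAN(x)) {
        // level unseen at this node during training: follow the heavier child
        goes_left = nl[i] >= nr[i];
      } else {
        goes_left = ((unsigned int)lmask[i] >> code) & 1u;
      }
    } else if (ISNAN(x)) {
      goes_left = nl[i] >= nr[i];
    } else {
      goes_left = x < split[i];
    }
    i = goes_left ? left[i] : right[i];
  }
  return i;
}

// [[Rcpp::export(name = ".tree_leaf_cpp")]]
IntegerVector tree_leaf_cpp(List tree, NumericMatrix X, LogicalVector is_cat) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"],
                nl = tree["n_left"], nr = tree["n_right"];
  NumericVector split = tree["split"], lmask = tree["lmask"], smask = tree["smask"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = route_row(var, split, lmask, smask, left, right, nl, nr, is_cat, X, r);
  return out;
}

// [[Rcpp::export(name = ".predict_trees_cpp")]]
NumericVector predict_trees_cpp(List trees, NumericMatrix X, LogicalVector is_cat,
                                double intercept, double learning_rate, int n_trees) {
  const int n = X.nrow();
  NumericVector out(n, intercept);
  const int T = std::min((int)trees.size(), n_trees);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"], left = tree["left"], right = tree["right"],
                  nl = tree["n_left"], nr = tree["n_right"];
    NumericVector split = tree["split"], lmask = tree["lmask"], smask = tree["smask"],
                  value = tree["value"];
    for (int r = 0; r < n; ++r) {
      const int leaf = route_row(var, split, lmask, smask, left, right, nl, nr,
                                 is_cat, X, r);
      out[r] += learning_rate * value[leaf];
    }
  }
  return out;
}
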
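#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Biased second-order (node2vec-style) random walks.
// `adj` is a list of 1-based neighbour index vectors, `wts` the matching
// edge weights. For each step from v (arrived via t) the unnormalised
// probability of neighbour x is alpha(t, x) * w_vx with alpha = 1/p when
// x == t, 1 when x is adjacent to t, 1/q otherwise.
// [[Rcpp::export]]
List simulate_walks_cpp(List adj, List wts, double p, double q,
                        int num_walks, int walk_length, int seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nbrs(n);
  std::vector<std::vector<double>> w(n);
  std::vector<std::unordered_set<int>> nbr_set(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ni = adj[i];
    NumericVector wi = wts[i];
    nbrs[i].assign(ni.begin(), ni.end());
    for (int &v : nbrs[i]) v -= 1;  // to 0-based
    w[i].assign(wi.begin(), wi.end());
    nbr_set[i].insert(nbrs[i].begin(), nbrs[i].end());
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  auto weighted_pick = [&](const std::vector<double> &probs) {
    double total = 0.0;
    for (double x : probs) total += x;
    double r = unif(rng) * total;
    double acc = 0.0;
    for (size_t i = 0; i < probs.size(); ++i) {
      acc += probs[i];
      if (r <= acc) return static_cast<int>(i);
    }
    return static_cast<int>(probs.size()) - 1;
  };

  List out;
  std::vector<double> probs;
  for (int iter = 0; iter < num_walks; ++iter) {
    for (int start = 0; start < n; ++start) {
      if (nbrs[start].empty()) continue;  // isolated nodes produce no walks
      IntegerVector walk(walk_length);
      walk[0] = start + 1;
      // first step: proportional to edge weight
      int prev = start;
      int cur = nbrs[start][weighted_pick(w[start])];
      walk[1] = cur + 1;
      for (int step = 2; step < walk_length; ++step) {
        const std::vector<int> &cn = nbrs[cur];
        probs.assign(cn.size(), 0.0);
        for (size_t j = 0; j < cn.size(); ++j) {
          int x = cn[j];
          double alpha;
          if (x == prev) alpha = 1.0 / p;
          else if (nbr_set[prev].count(x)) alpha = 1.0;
          else alpha = 1.0 / q;
          probs[j] = alpha * w[cur][j];
        }
        int nxt = cn[weighted_pick(probs)];
        walk[step] = nxt + 1;
        prev = cur;
        cur = nxt;
      }
      out.push_back(walk);
    }
  }
  return out;
}
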
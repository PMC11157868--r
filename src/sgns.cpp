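#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling over a random-walk corpus
// (word2vec-style). Node "words" are 1-based indices into an n_nodes
// vocabulary. Dynamic window shrinking, unigram^0.75 negative-sampling
// distribution, linearly decaying learning rate. Nodes never seen in the
// corpus keep zero vectors.
// [[Rcpp::export]]
NumericMatrix sgns_cpp(List walks, int n_nodes, int dim, int window,
                       int epochs, int negative, double lr, int seed) {
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  std::vector<double> freq(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector wk = walks[i];
    std::vector<int> row(wk.size());
    for (int j = 0; j < wk.size(); ++j) {
      row[j] = wk[j] - 1;
      freq[row[j]] += 1.0;
    }
    total_tokens += wk.size();
    corpus.push_back(std::move(row));
  }

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(n_nodes, 0.0);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    z += std::pow(freq[i], 0.75);
    cum[i] = z;
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> win_draw(1, window);

  auto draw_negative = [&]() {
    double r = unif(rng) * z;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> in_emb(static_cast<size_t>(n_nodes) * dim, 0.0);
  std::vector<double> out_emb(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (int i = 0; i < n_nodes; ++i) {
    if (freq[i] == 0.0) continue;
    for (int d = 0; d < dim; ++d) {
      in_emb[static_cast<size_t>(i) * dim + d] = (unif(rng) - 0.5) / dim;
    }
  }

  const double min_lr_frac = 1e-4;
  long long total_centers = static_cast<long long>(epochs) * total_tokens;
  long long processed = 0;
  std::vector<double> grad_center(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto &walk : corpus) {
      int len = static_cast<int>(walk.size());
      for (int i = 0; i < len; ++i) {
        double alpha = lr * (1.0 - static_cast<double>(processed) / total_centers);
        if (alpha < lr * min_lr_frac) alpha = lr * min_lr_frac;
        ++processed;
        int b = win_draw(rng);
        int center = walk[i];
        double *v = &in_emb[static_cast<size_t>(center) * dim];
        for (int j = std::max(0, i - b); j <= std::min(len - 1, i + b); ++j) {
          if (j == i) continue;
          std::fill(grad_center.begin(), grad_center.end(), 0.0);
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = walk[j];
              label = 1.0;
            } else {
              target = draw_negative();
              if (target == walk[j]) continue;
              label = 0.0;
            }
            double *u = &out_emb[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v[d] * u[d];
            double score = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - score) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad_center[d] += g * u[d];
              u[d] += g * v[d];
            }
          }
          for (int d = 0; d < dim; ++d) v[d] += grad_center[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    for (int d = 0; d < dim; ++d) {
      out(i, d) = in_emb[static_cast<size_t>(i) * dim + d];
    }
  }
  return out;
}
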
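// Multi-output random-forest regression for the numerical demultiplexer.
//
// Each tree partitions measurement space (p features, typically p = 3) by
// maximizing the variance reduction summed over all n outputs, so one tree
// predicts the whole reflectance spectrum at once; a leaf prediction is the
// mean training spectrum of the samples falling in the leaf.  Leaves store
// training-row indices (with bootstrap multiplicity) rather than dense
// n-vectors, keeping model size proportional to the training set.
//
// All randomness goes through a portable mt19937 stream seeded per tree, so
// a fixed seed gives bit-identical forests across platforms and runs.

#include <Rcpp.h>
#include <random>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Portable bounded draw in [0, m): fixed mapping of the raw 32-bit output,
// independent of the standard library's distribution implementations.
inline uint32_t draw_below(std::mt19937 &rng, uint32_t m) {
  return static_cast<uint32_t>((static_cast<uint64_t>(rng()) * m) >> 32);
}

struct TreeBuf {
  std::vector<int> var;              // split feature, -1 for leaf
  std::vector<double> split;         // split threshold
  std::vector<int> left, right;      // child node ids, -1 for leaf
  std::vector<int> leaf_start, leaf_len;  // into leaf_idx; -1/0 for internal
  std::vector<int> leaf_idx;         // training-row indices, with multiplicity
};

struct NodeJob {
  int node_id;
  int begin, end;   // range into the sample index workspace
  int depth;
};

void grow_tree(const NumericMatrix &X, const NumericMatrix &Y,
               std::vector<int> &samples, int mtry, int min_node,
               int max_depth, std::mt19937 &rng, TreeBuf &tree) {
  const int p = X.ncol(), n_out = Y.ncol();
  std::vector<int> feats(p);
  std::vector<double> sum_left(n_out), sum_total(n_out);
  std::vector<NodeJob> stack;

  auto new_node = [&]() {
    tree.var.push_back(-1);
    tree.split.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.leaf_start.push_back(-1);
    tree.leaf_len.push_back(0);
    return static_cast<int>(tree.var.size()) - 1;
  };

  stack.push_back({new_node(), 0, static_cast<int>(samples.size()), 0});

  std::vector<int> sorted;
  while (!stack.empty()) {
    NodeJob job = stack.back();
    stack.pop_back();
    const int sz = job.end - job.begin;

    bool try_split = sz > min_node && (max_depth <= 0 || job.depth < max_depth);

    int best_f = -1;
    double best_score = -1.0, best_thr = 0.0;

    if (try_split) {
      for (int f = 0; f < p; ++f) feats[f] = f;
      // partial Fisher-Yates: first mtry entries are the candidate features
      for (int f = 0; f < mtry; ++f) {
        int j = f + static_cast<int>(draw_below(rng, static_cast<uint32_t>(p - f)));
        std::swap(feats[f], feats[j]);
      }
      std::fill(sum_total.begin(), sum_total.end(), 0.0);
      for (int i = job.begin; i < job.end; ++i)
        for (int k = 0; k < n_out; ++k) sum_total[k] += Y(samples[i], k);

      for (int fi = 0; fi < mtry; ++fi) {
        const int f = feats[fi];
        sorted.assign(samples.begin() + job.begin, samples.begin() + job.end);
        std::sort(sorted.begin(), sorted.end(), [&](int a, int b) {
          return X(a, f) < X(b, f);
        });
        if (X(sorted.front(), f) == X(sorted.back(), f)) continue;  // constant
        std::fill(sum_left.begin(), sum_left.end(), 0.0);
        for (int i = 1; i < sz; ++i) {
          for (int k = 0; k < n_out; ++k) sum_left[k] += Y(sorted[i - 1], k);
          if (X(sorted[i - 1], f) == X(sorted[i], f)) continue;
          double score = 0.0;
          for (int k = 0; k < n_out; ++k) {
            const double sl = sum_left[k], sr = sum_total[k] - sl;
            score += sl * sl / i + sr * sr / (sz - i);
          }
          if (score > best_score) {
            best_score = score;
            best_f = f;
            best_thr = 0.5 * (X(sorted[i - 1], f) + X(sorted[i], f));
          }
        }
      }
    }

    if (best_f < 0) {  // leaf: no admissible split
      tree.leaf_start[job.node_id] = static_cast<int>(tree.leaf_idx.size());
      tree.leaf_len[job.node_id] = sz;
      for (int i = job.begin; i < job.end; ++i) tree.leaf_idx.push_back(samples[i]);
      continue;
    }

    // partition the workspace range in place
    int mid = job.begin;
    for (int i = job.begin; i < job.end; ++i)
      if (X(samples[i], best_f) <= best_thr) std::swap(samples[mid++], samples[i]);

    tree.var[job.node_id] = best_f;
    tree.split[job.node_id] = best_thr;
    const int lid = new_node(), rid = new_node();
    tree.left[job.node_id] = lid;
    tree.right[job.node_id] = rid;
    stack.push_back({lid, job.begin, mid, job.depth + 1});
    stack.push_back({rid, mid, job.end, job.depth + 1});
  }
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List cpp_grow_forest(NumericMatrix X, NumericMatrix Y, int n_trees, int mtry,
                     int min_node, int max_depth, double sample_fraction,
                     bool replace, int seed) {
  const int m = X.nrow();
  const int n_boot = std::max(1, static_cast<int>(std::lround(sample_fraction * m)));
  List out(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    // decorrelated, reproducible per-tree stream
    std::mt19937 rng(static_cast<uint32_t>(
        (static_cast<uint64_t>(static_cast<uint32_t>(seed)) +
         0x9E3779B9ull * static_cast<uint64_t>(t + 1)) & 0xFFFFFFFFull));
    std::vector<int> samples;
    samples.reserve(n_boot);
    if (replace) {
      for (int i = 0; i < n_boot; ++i)
        samples.push_back(static_cast<int>(draw_below(rng, static_cast<uint32_t>(m))));
    } else {
      std::vector<int> all(m);
      for (int i = 0; i < m; ++i) all[i] = i;
      for (int i = 0; i < n_boot; ++i) {
        int j = i + static_cast<int>(draw_below(rng, static_cast<uint32_t>(m - i)));
        std::swap(all[i], all[j]);
      }
      samples.assign(all.begin(), all.begin() + n_boot);
    }

    TreeBuf tree;
    grow_tree(X, Y, samples, mtry, min_node, max_depth, rng, tree);
    out[t] = List::create(
        _["var"] = wrap(tree.var), _["split"] = wrap(tree.split),
        _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
        _["leaf_start"] = wrap(tree.leaf_start),
        _["leaf_len"] = wrap(tree.leaf_len),
        _["leaf_idx"] = wrap(tree.leaf_idx));
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_predict_forest(List trees, NumericMatrix X, NumericMatrix Y) {
  const int m = X.nrow(), n_out = Y.ncol(), n_trees = trees.size();
  NumericMatrix pred(m, n_out);

  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    IntegerVector leaf_start = tr["leaf_start"], leaf_len = tr["leaf_len"];
    IntegerVector leaf_idx = tr["leaf_idx"];
    NumericVector split = tr["split"];

    for (int i = 0; i < m; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
      const int start = leaf_start[node], len = leaf_len[node];
      const double w = 1.0 / (static_cast<double>(len) * n_trees);
      for (int j = 0; j < len; ++j) {
        const int row = leaf_idx[start + j];
        for (int k = 0; k < n_out; ++k) pred(i, k) += w * Y(row, k);
      }
    }
  }
  return pred;
}
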
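#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained RNG (xorshift64*) so restarts are reproducible across
// platforms and independent of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform on {0, ..., n-1}; modulo bias is negligible for n << 2^64
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// Draw k distinct indices from 0..n-1 (partial Fisher-Yates).
static void sample_distinct(XorShift &rng, int n, int k, std::vector<int> &out) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  out.resize(k);
  for (int i = 0; i < k; ++i) {
    int j = i + rng.below(n - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// number of k-subsets of n, capped to avoid overflow
static double n_choose_k(int n, int k) {
  double r = 1.0;
  for (int i = 1; i <= k; ++i) {
    r *= static_cast<double>(n - k + i) / i;
    if (r > 1e9) return 1e9;
  }
  return r;
}

// One PAM-style alternation run from random medoids: assign each point to its
// nearest medoid, recompute each cluster's medoid as the member minimizing the
// within-cluster distance sum, repeat until the medoid set is stable.
static double kmedoids_once(const NumericMatrix &d, int k,
                            std::vector<int> &labels, std::vector<int> &medoids,
                            int max_iter) {
  const int n = d.nrow();
  labels.assign(n, 0);
  std::vector<int> size(k);
  double cost = 0.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    // assignment step (ties -> lowest medoid index; medoids stay home so
    // duplicate points cannot silently empty a cluster)
    std::fill(size.begin(), size.end(), 0);
    cost = 0.0;
    for (int i = 0; i < n; ++i) {
      int best = 0; double bd = d(i, medoids[0]);
      for (int c = 1; c < k; ++c) {
        double dc = d(i, medoids[c]);
        if (dc < bd) { bd = dc; best = c; }
      }
      for (int c = 0; c < k; ++c) if (medoids[c] == i) { best = c; bd = 0.0; }
      labels[i] = best; size[best]++; cost += bd;
    }
    // update step
    bool changed = false;
    for (int c = 0; c < k; ++c) {
      int best_m = -1; double best_sum = R_PosInf;
      for (int i = 0; i < n; ++i) {
        if (labels[i] != c) continue;
        double s = 0.0;
        for (int j = 0; j < n; ++j) if (labels[j] == c) s += d(i, j);
        if (s < best_sum) { best_sum = s; best_m = i; }
      }
      if (best_m >= 0 && best_m != medoids[c]) { medoids[c] = best_m; changed = true; }
    }
    if (!changed) break;
  }
  // final assignment against the settled medoids
  cost = 0.0;
  for (int i = 0; i < n; ++i) {
    int best = 0; double bd = d(i, medoids[0]);
    for (int c = 1; c < k; ++c) {
      double dc = d(i, medoids[c]);
      if (dc < bd) { bd = dc; best = c; }
    }
    for (int c = 0; c < k; ++c) if (medoids[c] == i) { best = c; bd = 0.0; }
    labels[i] = best; cost += bd;
  }
  return cost;
}

// [[Rcpp::export(rng = false)]]
List kmedoids_cpp(NumericMatrix d, int k, int n_init, double seed) {
  const int n = d.nrow();
  XorShift rng(static_cast<uint64_t>(seed) + 0x51ED270B9ULL);
  std::vector<int> labels, medoids, best_labels, best_medoids;
  double best_cost = R_PosInf;
  const int max_iter = n * k + 1;
  if (n_choose_k(n, k) <= 256.0) {
    // small problem: run the alternation from every medoid subset, which
    // guarantees the global optimum (the run started at the optimal subset
    // can only keep or improve its cost)
    std::vector<int> combo(k);
    for (int i = 0; i < k; ++i) combo[i] = i;
    while (true) {
      medoids = combo;
      double cost = kmedoids_once(d, k, labels, medoids, max_iter);
      if (cost < best_cost - 1e-12) {
        best_cost = cost; best_labels = labels; best_medoids = medoids;
      }
      int i = k - 1;
      while (i >= 0 && combo[i] == n - k + i) --i;
      if (i < 0) break;
      ++combo[i];
      for (int j = i + 1; j < k; ++j) combo[j] = combo[j - 1] + 1;
    }
  } else {
    for (int r = 0; r < n_init; ++r) {
      sample_distinct(rng, n, k, medoids);
      double cost = kmedoids_once(d, k, labels, medoids, max_iter);
      if (cost < best_cost - 1e-12) {
        best_cost = cost; best_labels = labels; best_medoids = medoids;
      }
    }
  }
  // relabel clusters 1..k by order of first appearance so labels are canonical
  IntegerVector lab(n); std::vector<int> map(k, 0); int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int c = best_labels[i];
    if (map[c] == 0) map[c] = ++next_id;
    lab[i] = map[c];
  }
  IntegerVector med(k);
  for (int c = 0; c < k; ++c) med[map[c] - 1] = best_medoids[c] + 1;
  return List::create(_["labels"] = lab, _["medoids"] = med, _["cost"] = best_cost);
}
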
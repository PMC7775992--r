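// Dense modularity maximisation.
//
// Both routines operate on a generic symmetric score matrix B and maximise
// sum_{u,v: g_u == g_v} B[u, v] over partitions g. The multislice quality
// matrix (intra-layer modularity blocks plus ordinal inter-layer coupling)
// is assembled in R; keeping the optimiser generic lets the exhaustive
// enumerator double as an independent check on small instances.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>

using namespace Rcpp;

// One Louvain level: greedy local moves on dense B until no move improves.
// Returns true if anything moved. labels are 0-based, dense at exit.
static bool local_moves(const std::vector<double>& B, int n,
                        std::vector<int>& g, std::mt19937& rng) {
  bool any_move = false;
  bool improved = true;
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  std::vector<double> comm_sum(n);
  int sweeps = 0;
  while (improved && sweeps < 200) {
    improved = false;
    ++sweeps;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      std::fill(comm_sum.begin(), comm_sum.end(), 0.0);
      const double* row = &B[(size_t)v * n];
      for (int u = 0; u < n; ++u) {
        if (u == v) continue;
        comm_sum[g[u]] += row[u];
      }
      int cur = g[v];
      double best_gain = 0.0;
      int best_c = cur;
      double base = comm_sum[cur];
      for (int c = 0; c < n; ++c) {
        if (c == cur) continue;
        double gain = comm_sum[c] - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_c = c;
        }
      }
      if (best_c != cur) {
        g[v] = best_c;
        improved = true;
        any_move = true;
      }
    }
  }
  // dense relabel
  std::vector<int> remap(n, -1);
  int k = 0;
  for (int v = 0; v < n; ++v) {
    if (remap[g[v]] < 0) remap[g[v]] = k++;
    g[v] = remap[g[v]];
  }
  return any_move;
}

static double partition_score(const std::vector<double>& B, int n,
                              const std::vector<int>& g) {
  double s = 0.0;
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      if (g[u] == g[v]) s += B[(size_t)u * n + v];
  return s;
}

// [[Rcpp::export]]
List cpp_louvain_dense(NumericMatrix Bmat, int seed,
                       Nullable<IntegerVector> init = R_NilValue) {
  int n = Bmat.nrow();
  if (Bmat.ncol() != n) stop("B must be square");
  std::vector<double> B(Bmat.begin(), Bmat.end());
  std::mt19937 rng((unsigned)seed);

  // initial assignment: singletons, or a caller-supplied seed partition
  // (e.g. the static mean-network communities replicated across layers)
  std::vector<int> assign(n);
  std::iota(assign.begin(), assign.end(), 0);
  std::vector<double> curB = B;
  int curN = n;
  std::vector<int> init_labels;
  if (init.isNotNull()) {
    IntegerVector iv(init);
    if ((int)iv.size() != n) stop("init length must match B");
    std::vector<int> remap0(n, -1);
    int k0 = 0;
    init_labels.resize(n);
    for (int v = 0; v < n; ++v) {
      int c = iv[v] - 1;
      if (c < 0 || c >= n) stop("init labels out of range");
      if (remap0[c] < 0) remap0[c] = k0++;
      init_labels[v] = remap0[c];
    }
  }

  for (int level = 0; level < 64; ++level) {
    std::vector<int> lg(curN);
    if (level == 0 && !init_labels.empty()) {
      lg = init_labels;   // element-level local moves start from the seed
    } else {
      std::iota(lg.begin(), lg.end(), 0);
    }
    bool seeded = (level == 0 && !init_labels.empty());
    bool moved = local_moves(curB, curN, lg, rng);
    // propagate to original nodes
    for (int v = 0; v < n; ++v) assign[v] = lg[assign[v]];
    int k = 0;
    for (int c : lg) k = std::max(k, c + 1);
    if ((!moved && !seeded) || k == curN) break;
    // aggregate B
    std::vector<double> aggB((size_t)k * k, 0.0);
    for (int u = 0; u < curN; ++u)
      for (int v = 0; v < curN; ++v)
        aggB[(size_t)lg[u] * k + lg[v]] += curB[(size_t)u * curN + v];
    curB.swap(aggB);
    curN = k;
  }

  // dense relabel of final assignment, 1-based for R
  std::vector<int> remap(n, -1);
  int k = 0;
  IntegerVector labels(n);
  for (int v = 0; v < n; ++v) {
    if (remap[assign[v]] < 0) remap[assign[v]] = k++;
    labels[v] = remap[assign[v]] + 1;
  }
  std::vector<int> gfinal(n);
  for (int v = 0; v < n; ++v) gfinal[v] = labels[v] - 1;
  double score = partition_score(B, n, gfinal);
  return List::create(_["labels"] = labels, _["score"] = score,
                      _["n_communities"] = k);
}

// Exhaustive maximum over all set partitions via restricted growth strings.
// Feasible up to ~13 elements (Bell(13) ~ 2.8e7). Used as the independent
// optimality oracle on small multislice instances.
// [[Rcpp::export]]
List cpp_exhaustive_best(NumericMatrix Bmat, int max_elements = 14) {
  int n = Bmat.nrow();
  if (Bmat.ncol() != n) stop("B must be square");
  if (n > max_elements) stop("instance too large for exhaustive search");
  std::vector<double> B(Bmat.begin(), Bmat.end());

  double diag_sum = 0.0;
  for (int v = 0; v < n; ++v) diag_sum += B[(size_t)v * n + v];

  std::vector<int> g(n, 0), best_g(n, 0);
  double best = -std::numeric_limits<double>::infinity();
  // DFS over restricted growth strings with incremental off-diagonal score
  std::vector<double> stack_score(n + 1, 0.0);
  std::vector<int> maxlab(n + 1, 0); // labels used among first i elements
  int i = 0;
  g[0] = 0;
  maxlab[0] = 0;
  std::vector<int> choice(n, 0);
  choice[0] = 0;
  while (i >= 0) {
    if (i == n) {
      double total = stack_score[n] + diag_sum;
      if (total > best) {
        best = total;
        best_g = g;
      }
      --i;
      if (i >= 0) ++choice[i];
      continue;
    }
    int limit = (i == 0) ? 0 : maxlab[i]; // labels 0..limit allowed
    if (choice[i] > limit) {
      choice[i] = 0;
      --i;
      if (i >= 0) ++choice[i];
      continue;
    }
    int c = choice[i];
    g[i] = c;
    double add = 0.0;
    const double* row = &B[(size_t)i * n];
    for (int j = 0; j < i; ++j)
      if (g[j] == c) add += 2.0 * row[j];
    stack_score[i + 1] = stack_score[i] + add;
    maxlab[i + 1] = std::max(maxlab[i], c + 1);
    ++i;
    if (i < n) choice[i] = 0;
  }

  IntegerVector labels(n);
  for (int v = 0; v < n; ++v) labels[v] = best_g[v] + 1;
  return List::create(_["labels"] = labels, _["score"] = best);
}
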
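// Single-threaded LINE-style embedding trainer with negative edge sampling.
// Deterministic for a fixed seed: edges are drawn from an alias table built
// over edge weights, negatives from an alias table over degree^0.75, and
// all updates are applied sequentially with a linearly decaying step size.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct Alias {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double>& w) {
    int n = w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double tot = 0.0;
    for (double x : w) tot += x;
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / tot;
    std::vector<int> small, large;
    for (int i = n - 1; i >= 0; --i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = p[l] + p[s] - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  int draw(std::mt19937& rng, std::uniform_real_distribution<double>& unif) const {
    int n = prob.size();
    double r = unif(rng) * n;
    int i = (int)r;
    if (i >= n) i = n - 1;
    return (r - i) < prob[i] ? i : alias[i];
  }
};

inline double sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".line_sgd")]]
NumericMatrix line_sgd(IntegerVector from, IntegerVector to,
                       NumericVector weight, int n_vertices, int order,
                       int dim, int negatives, double rho0,
                       double total_samples, int seed) {
  int m = from.size();
  if (m == 0) stop("empty edge list");

  // store each undirected edge in both directions for source sampling
  std::vector<int> src(2 * m), dst(2 * m);
  std::vector<double> ew(2 * m);
  std::vector<double> deg(n_vertices, 0.0);
  for (int e = 0; e < m; ++e) {
    src[2 * e] = from[e]; dst[2 * e] = to[e];
    src[2 * e + 1] = to[e]; dst[2 * e + 1] = from[e];
    ew[2 * e] = ew[2 * e + 1] = weight[e];
    deg[from[e]] += weight[e];
    deg[to[e]] += weight[e];
  }
  Alias edge_alias; edge_alias.build(ew);
  std::vector<double> noise(n_vertices);
  for (int v = 0; v < n_vertices; ++v) noise[v] = std::pow(deg[v], 0.75);
  Alias neg_alias; neg_alias.build(noise);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // vertex vectors; context vectors only for order 2
  std::vector<double> emb((size_t)n_vertices * dim);
  std::vector<double> ctx;
  for (auto& x : emb) x = (unif(rng) - 0.5) / dim;
  if (order == 2) ctx.assign((size_t)n_vertices * dim, 0.0);

  std::vector<double> grad(dim);
  long long total = (long long)total_samples;
  for (long long t = 0; t < total; ++t) {
    double rho = rho0 * (1.0 - (double)t / total);
    if (rho < rho0 * 1e-4) rho = rho0 * 1e-4;
    int e = edge_alias.draw(rng, unif);
    int u = src[e], v = dst[e];
    double* vu = &emb[(size_t)u * dim];
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int d = 0; d <= negatives; ++d) {
      int target;
      double label;
      if (d == 0) { target = v; label = 1.0; }
      else {
        target = neg_alias.draw(rng, unif);
        if (target == u || target == v) continue;
        label = 0.0;
      }
      double* vt = (order == 1) ? &emb[(size_t)target * dim]
                                : &ctx[(size_t)target * dim];
      double dot = 0.0;
      for (int i = 0; i < dim; ++i) dot += vu[i] * vt[i];
      double g = (label - sigmoid(dot)) * rho;
      for (int i = 0; i < dim; ++i) {
        grad[i] += g * vt[i];
        vt[i] += g * vu[i];
      }
    }
    for (int i = 0; i < dim; ++i) vu[i] += grad[i];
  }

  NumericMatrix out(n_vertices, dim);
  for (int v = 0; v < n_vertices; ++v)
    for (int i = 0; i < dim; ++i) out(v, i) = emb[(size_t)v * dim + i];
  return out;
}

// [[Rcpp::export(name = ".line_objective")]]
double line_objective(IntegerVector from, IntegerVector to,
                      NumericVector weight, NumericMatrix emb) {
  // first-order objective: -sum_e w * log sigmoid(u_i . u_j)
  double o = 0.0;
  int dim = emb.ncol();
  for (int e = 0; e < from.size(); ++e) {
    double dot = 0.0;
    for (int i = 0; i < dim; ++i) dot += emb(from[e], i) * emb(to[e], i);
    double s = sigmoid(dot);
    if (s < 1e-12) s = 1e-12;
    o -= weight[e] * std::log(s);
  }
  return o;
}
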
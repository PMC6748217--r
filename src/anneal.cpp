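#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// Weighted linear arrangement cost: sum over edges of |pos[u] - pos[v]|.
// Edge endpoints are 0-based vertex indices; pos maps vertex -> position.
static double arrangement_cost(const std::vector<int> &ei,
                               const std::vector<int> &ej,
                               const std::vector<int> &pos) {
  double cost = 0.0;
  for (size_t e = 0; e < ei.size(); ++e)
    cost += std::abs(pos[ei[e]] - pos[ej[e]]);
  return cost;
}

// Cost contribution of all edges incident to vertex v (adjacency in CSR form).
static double incident_cost(int v, const std::vector<int> &adj,
                            const std::vector<int> &adj_start,
                            const std::vector<int> &pos) {
  double c = 0.0;
  for (int k = adj_start[v]; k < adj_start[v + 1]; ++k)
    c += std::abs(pos[v] - pos[adj[k]]);
  return c;
}

// [[Rcpp::export(name = ".anneal_order_cpp")]]
List anneal_order_cpp(IntegerVector edge_i, IntegerVector edge_j, int n,
                      IntegerVector init_pos, int n_steps, double t0,
                      double cooling, int cool_every, int seed) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<int> pos(init_pos.begin(), init_pos.end());

  // CSR adjacency
  std::vector<int> deg(n, 0);
  for (size_t e = 0; e < ei.size(); ++e) {
    deg[ei[e]]++;
    deg[ej[e]]++;
  }
  std::vector<int> adj_start(n + 1, 0);
  for (int v = 0; v < n; ++v) adj_start[v + 1] = adj_start[v] + deg[v];
  std::vector<int> adj(adj_start[n]);
  std::vector<int> fill(adj_start.begin(), adj_start.end() - 1);
  for (size_t e = 0; e < ei.size(); ++e) {
    adj[fill[ei[e]]++] = ej[e];
    adj[fill[ej[e]]++] = ei[e];
  }

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double cost = arrangement_cost(ei, ej, pos);
  const double init_cost = cost;
  std::vector<int> best_pos(pos);
  double best_cost = cost;

  // Temperature probe: if t0 <= 0, set it so a median uphill move is
  // accepted with probability ~0.5 over a 100-proposal probe.
  double temp = t0;
  if (temp <= 0.0) {
    std::vector<double> uphill;
    for (int p = 0; p < 100; ++p) {
      int u = pick(rng), w = pick(rng);
      if (u == w) continue;
      double before = incident_cost(u, adj, adj_start, pos) +
                      incident_cost(w, adj, adj_start, pos);
      std::swap(pos[u], pos[w]);
      double after = incident_cost(u, adj, adj_start, pos) +
                     incident_cost(w, adj, adj_start, pos);
      std::swap(pos[u], pos[w]);  // undo
      double delta = after - before;
      if (delta > 0) uphill.push_back(delta);
    }
    if (uphill.empty()) {
      temp = 1.0;
    } else {
      std::nth_element(uphill.begin(), uphill.begin() + uphill.size() / 2,
                       uphill.end());
      temp = uphill[uphill.size() / 2] / std::log(2.0);
    }
  }

  int trace_every = std::max(1, n_steps / 200);
  std::vector<double> trace;
  trace.push_back(best_cost);

  for (int step = 0; step < n_steps; ++step) {
    int u = pick(rng), w = pick(rng);
    if (u != w) {
      double before = incident_cost(u, adj, adj_start, pos) +
                      incident_cost(w, adj, adj_start, pos);
      std::swap(pos[u], pos[w]);
      double after = incident_cost(u, adj, adj_start, pos) +
                     incident_cost(w, adj, adj_start, pos);
      double delta = after - before;
      if (delta <= 0.0 || unif(rng) < std::exp(-delta / temp)) {
        cost += delta;
        if (cost < best_cost) {
          best_cost = cost;
          best_pos = pos;
        }
      } else {
        std::swap(pos[u], pos[w]);  // reject
      }
    }
    if (cool_every > 0 && (step + 1) % cool_every == 0) temp *= cooling;
    if ((step + 1) % trace_every == 0) trace.push_back(best_cost);
  }

  return List::create(_["pos"] = IntegerVector(best_pos.begin(), best_pos.end()),
                      _["cost"] = best_cost, _["init_cost"] = init_cost,
                      _["t0"] = temp, _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Exact minimum linear arrangement by permutation enumeration. Only feasible
// for small n (n <= 10 enforced on the R side).
// [[Rcpp::export(name = ".exact_mla_cpp")]]
double exact_mla_cpp(IntegerVector edge_i, IntegerVector edge_j, int n) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<int> pos(n);
  for (int v = 0; v < n; ++v) pos[v] = v;
  double best = arrangement_cost(ei, ej, pos);
  while (std::next_permutation(pos.begin(), pos.end())) {
    double c = arrangement_cost(ei, ej, pos);
    if (c < best) best = c;
  }
  return best;
}
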
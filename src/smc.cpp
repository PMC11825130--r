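// Sequentially Markov coalescent along a chromosome with piecewise-constant
// Ne (McVean & Cardin SMC). The marginal genealogy at every position is a
// standard coalescent tree; prune-regraft moves at recombination breakpoints
// give smoothly decaying linkage. Uses R's RNG so results are reproducible
// under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Epochs {
  std::vector<double> start;  // generations before present, first = 0
  std::vector<double> ne;     // diploid effective sizes
  double ne_at(double t) const {
    size_t i = start.size() - 1;
    while (i > 0 && start[i] > t) --i;
    return ne[i];
  }
};

struct Tree {
  int n;                       // tips 0..n-1; internal n..2n-2
  std::vector<int> parent;     // -1 = none (root)
  std::vector<int> child1, child2;
  std::vector<double> time;
  int root;
};

// waiting time to the next coalescence among k lineages, starting at t
double coal_wait(int k, double t, const Epochs& ep) {
  double rate_scale = k * (k - 1) / 2.0;
  for (;;) {
    size_t i = ep.start.size() - 1;
    while (i > 0 && ep.start[i] > t) --i;
    double rate = rate_scale / (2.0 * ep.ne[i]);
    double dt = R::rexp(1.0 / rate);
    double bound = (i + 1 < ep.start.size()) ? ep.start[i + 1] : R_PosInf;
    if (t + dt <= bound) return t + dt;
    t = bound;
  }
}

Tree init_tree(int n, const Epochs& ep) {
  Tree tr;
  tr.n = n;
  int m = 2 * n - 1;
  tr.parent.assign(m, -1);
  tr.child1.assign(m, -1);
  tr.child2.assign(m, -1);
  tr.time.assign(m, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  for (int e = 0; e < n - 1; ++e) {
    int k = n - e;
    t = coal_wait(k, t, ep);
    int v = n + e;
    tr.time[v] = t;
    int i1 = (int)(unif_rand() * k);
    int c1 = active[i1];
    active[i1] = active[k - 1];
    int i2 = (int)(unif_rand() * (k - 1));
    int c2 = active[i2];
    active[i2] = v;
    tr.parent[c1] = v;
    tr.parent[c2] = v;
    tr.child1[v] = c1;
    tr.child2[v] = c2;
  }
  tr.root = 2 * n - 2;
  return tr;
}

// collect all nodes of the subtree rooted at v into out
void nodes_below(const Tree& tr, int v, std::vector<int>& out) {
  std::vector<int> stack{v};
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    out.push_back(x);
    if (x >= tr.n) {
      stack.push_back(tr.child1[x]);
      stack.push_back(tr.child2[x]);
    }
  }
}

// tips of the subtree rooted at v (1-based for R)
void tips_below(const Tree& tr, int v, std::vector<int>& out) {
  std::vector<int> stack{v};
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    if (x < tr.n) out.push_back(x + 1);
    else {
      stack.push_back(tr.child1[x]);
      stack.push_back(tr.child2[x]);
    }
  }
}

// re-coalescence time of a floating lineage starting at `from`, against a
// remaining tree with n_rem tips and sorted internal node times rem_times
double recoal_time(double from, const std::vector<double>& rem_times,
                   int n_rem, const Epochs& ep) {
  // hazard breakpoints: remaining-tree internal times and epoch starts > from
  std::vector<double> grid;
  for (double tt : rem_times) if (tt > from) grid.push_back(tt);
  for (double s : ep.start) if (s > from) grid.push_back(s);
  std::sort(grid.begin(), grid.end());
  double target = R::rexp(1.0);
  double acc = 0.0, t0 = from;
  size_t gi = 0;
  for (;;) {
    double t1 = (gi < grid.size()) ? grid[gi] : R_PosInf;
    while (gi < grid.size() && grid[gi] <= t0) { ++gi; t1 = (gi < grid.size()) ? grid[gi] : R_PosInf; }
    int done = (int)(std::upper_bound(rem_times.begin(), rem_times.end(), t0)
                     - rem_times.begin());
    int k = n_rem - done;
    if (k < 1) k = 1;  // above the remaining root
    double lambda = k / (2.0 * ep.ne_at(t0));
    double seg = (t1 - t0) * lambda;
    if (acc + seg >= target) return t0 + (target - acc) / lambda;
    acc += seg;
    t0 = t1;
    ++gi;
  }
}

void recombine(Tree& tr, const Epochs& ep) {
  int m = 2 * tr.n - 1;
  // choose a branch proportionally to length
  std::vector<int> nodes;
  std::vector<double> cum;
  double total = 0.0;
  for (int v = 0; v < m; ++v) {
    if (tr.parent[v] < 0) continue;
    total += tr.time[tr.parent[v]] - tr.time[v];
    nodes.push_back(v);
    cum.push_back(total);
  }
  double upick = unif_rand() * total;
  int b = nodes[std::lower_bound(cum.begin(), cum.end(), upick) - cum.begin()];
  double u = R::runif(tr.time[b], tr.time[tr.parent[b]]);
  // splice out p (parent of b)
  int p = tr.parent[b];
  int sib = (tr.child1[p] == b) ? tr.child2[p] : tr.child1[p];
  int g = tr.parent[p];
  if (g < 0) {
    tr.parent[sib] = -1;
    tr.root = sib;
  } else {
    tr.parent[sib] = g;
    if (tr.child1[g] == p) tr.child1[g] = sib; else tr.child2[g] = sib;
  }
  tr.parent[b] = -1;
  // remaining tree = all nodes except subtree(b) and p
  std::vector<int> removed;
  nodes_below(tr, b, removed);
  removed.push_back(p);
  std::vector<char> is_removed(m, 0);
  for (int v : removed) is_removed[v] = 1;
  std::vector<double> rem_times;
  int n_rem = 0;
  for (int v = 0; v < m; ++v) {
    if (is_removed[v]) continue;
    if (v < tr.n) ++n_rem;
    else rem_times.push_back(tr.time[v]);
  }
  std::sort(rem_times.begin(), rem_times.end());
  double tnew = recoal_time(u, rem_times, n_rem, ep);
  // attach target: branch of the remaining tree crossing tnew
  int target;
  if (tnew >= tr.time[tr.root]) {
    target = tr.root;
  } else {
    std::vector<int> cand;
    for (int v = 0; v < m; ++v) {
      if (is_removed[v] || v == tr.root) continue;
      if (tr.time[v] <= tnew && tr.time[tr.parent[v]] > tnew)
        cand.push_back(v);
    }
    if (cand.empty()) target = tr.root;
    else target = cand[(int)(unif_rand() * cand.size())];
  }
  // re-insert p at tnew joining b and target
  tr.time[p] = tnew;
  tr.child1[p] = b;
  tr.child2[p] = target;
  tr.parent[b] = p;
  int gp = tr.parent[target];
  if (target == tr.root) {
    tr.parent[target] = p;
    tr.parent[p] = -1;
    tr.root = p;
  } else {
    if (tr.child1[gp] == target) tr.child1[gp] = p; else tr.child2[gp] = p;
    tr.parent[p] = gp;
    tr.parent[target] = p;
  }
}

}  // namespace

// [[Rcpp::export(name = ".smc_simulate_cpp")]]
List smc_simulate_cpp(int n, double L, double mu, double r,
                      NumericVector epoch_starts, NumericVector epoch_nes) {
  Epochs ep;
  ep.start = as<std::vector<double>>(epoch_starts);
  ep.ne = as<std::vector<double>>(epoch_nes);
  Tree tr = init_tree(n, ep);
  std::vector<double> positions;
  std::vector<std::vector<int>> carriers;
  double x = 0.0;
  int m = 2 * n - 1;
  for (;;) {
    double ttot = 0.0;
    for (int v = 0; v < m; ++v)
      if (tr.parent[v] >= 0) ttot += tr.time[tr.parent[v]] - tr.time[v];
    double dx = (r > 0) ? R::rexp(1.0 / (r * ttot)) : R_PosInf;
    double seg_end = std::min(x + dx, L);
    double seg_len = seg_end - x;
    int nmut = (int)R::rpois(mu * seg_len * ttot);
    if (nmut > 0) {
      // branch cumulative lengths for this marginal tree
      std::vector<int> nodes;
      std::vector<double> cum;
      double total = 0.0;
      for (int v = 0; v < m; ++v) {
        if (tr.parent[v] < 0) continue;
        total += tr.time[tr.parent[v]] - tr.time[v];
        nodes.push_back(v);
        cum.push_back(total);
      }
      for (int j = 0; j < nmut; ++j) {
        double upick = unif_rand() * total;
        int b = nodes[std::lower_bound(cum.begin(), cum.end(), upick)
                      - cum.begin()];
        double pos = x + unif_rand() * seg_len;
        std::vector<int> tips;
        tips_below(tr, b, tips);
        if (tips.empty() || (int)tips.size() == n) continue;
        positions.push_back(pos);
        carriers.push_back(tips);
      }
    }
    if (seg_end >= L) break;
    x = seg_end;
    recombine(tr, ep);
  }
  List car(carriers.size());
  for (size_t i = 0; i < carriers.size(); ++i)
    car[i] = wrap(carriers[i]);
  return List::create(_["pos"] = wrap(positions), _["carriers"] = car);
}
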
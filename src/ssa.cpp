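// Exact stochastic simulation of mass-action reaction networks using the
// Gibson-Bruck next-reaction method: putative firing times in an indexed
// binary min-heap, a reaction dependency graph, and time rescaling of
// unfired reactions. Counter-based RNG keeps runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

struct Heap {
  std::vector<int> heap;   // heap position -> reaction
  std::vector<int> pos;    // reaction -> heap position
  std::vector<double> key; // reaction -> putative time
  void init(int n) {
    heap.resize(n); pos.resize(n); key.assign(n, R_PosInf);
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  void swap_nodes(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void up(int i) {
    while (i > 0) {
      int par = (i - 1) / 2;
      if (key[heap[i]] < key[heap[par]]) { swap_nodes(i, par); i = par; }
      else break;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && key[heap[l]] < key[heap[m]]) m = l;
      if (r < n && key[heap[r]] < key[heap[m]]) m = r;
      if (m == i) break;
      swap_nodes(i, m); i = m;
    }
  }
  void update(int reaction, double t) {
    double old = key[reaction];
    key[reaction] = t;
    if (t < old) up(pos[reaction]); else down(pos[reaction]);
  }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

static double propensity(const IntegerMatrix& reac, const std::vector<double>& x,
                         double rate, int r) {
  double a = rate;
  for (int s = 0; s < reac.ncol(); ++s) {
    int k = reac(r, s);
    for (int m = 0; m < k; ++m) a *= std::max(x[s] - m, 0.0) / (m + 1.0);
  }
  return a;
}

// [[Rcpp::export]]
List cpp_ssa_run(IntegerVector x0, IntegerMatrix reac, IntegerMatrix prod,
                 NumericVector rates, double T, int seed,
                 NumericVector out_times, int max_events = 10000000,
                 bool log_events = false) {
  int ns = x0.size(), nr = reac.nrow();
  if (prod.nrow() != nr || (int)rates.size() != nr)
    stop("stoichiometry/rate dimensions disagree");
  std::vector<double> x(ns);
  for (int s = 0; s < ns; ++s) x[s] = x0[s];

  // dependency graph: r affects q if any species with net change in r is a
  // reactant of q (self-dependency always included)
  std::vector<std::vector<int>> dep(nr);
  for (int r = 0; r < nr; ++r) {
    for (int q = 0; q < nr; ++q) {
      if (q == r) { dep[r].push_back(q); continue; }
      bool hit = false;
      for (int s = 0; s < ns && !hit; ++s) {
        if (prod(r, s) - reac(r, s) != 0 && reac(q, s) > 0) hit = true;
      }
      if (hit) dep[r].push_back(q);
    }
  }

  std::vector<double> a(nr);
  std::vector<uint64_t> draws(nr, 0);
  Heap h; h.init(nr);
  for (int r = 0; r < nr; ++r) {
    a[r] = propensity(reac, x, rates[r], r);
    if (!std::isfinite(a[r])) stop("non-finite propensity at initialisation");
    double u = u01((uint64_t)seed, 0ULL, (uint64_t)r, draws[r]++);
    h.update(r, a[r] > 0 ? -std::log(u) / a[r] : R_PosInf);
  }

  int n_out = out_times.size();
  NumericMatrix states(n_out, ns);
  int out_i = 0;
  std::vector<double> ev_t; std::vector<int> ev_r;
  double t = 0.0;
  long long n_events = 0;

  auto flush_outputs = [&](double tnow) {
    while (out_i < n_out && out_times[out_i] <= tnow) {
      for (int s = 0; s < ns; ++s) states(out_i, s) = x[s];
      ++out_i;
    }
  };

  for (;;) {
    double tnext = h.top_key();
    if (!std::isfinite(tnext) || tnext > T) break;
    int mu = h.top();
    flush_outputs(tnext);
    t = tnext;
    for (int s = 0; s < ns; ++s) x[s] += prod(mu, s) - reac(mu, s);
    if (log_events) { ev_t.push_back(t); ev_r.push_back(mu + 1); }
    if (++n_events > max_events) stop("event budget exceeded (%d)", max_events);
    for (int q : dep[mu]) {
      double a_new = propensity(reac, x, rates[q], q);
      if (!std::isfinite(a_new) || a_new > 1e300)
        stop("propensity overflow in reaction %d", q + 1);
      double t_new;
      if (q == mu || a[q] <= 0.0 || !std::isfinite(h.key[q])) {
        double u = u01((uint64_t)seed, (uint64_t)n_events, (uint64_t)q, draws[q]++);
        t_new = a_new > 0 ? t - std::log(u) / a_new : R_PosInf;
      } else {
        t_new = a_new > 0 ? t + (a[q] / a_new) * (h.key[q] - t) : R_PosInf;
      }
      a[q] = a_new;
      h.update(q, t_new);
    }
  }
  flush_outputs(T + 1e-300);
  // pad any remaining outputs with the final state
  for (; out_i < n_out; ++out_i)
    for (int s = 0; s < ns; ++s) states(out_i, s) = x[s];

  IntegerVector xf(ns);
  for (int s = 0; s < ns; ++s) xf[s] = (int)x[s];
  List out = List::create(_["final_state"] = xf, _["final_time"] = t,
                          _["n_events"] = (double)n_events,
                          _["states"] = states);
  if (log_events) {
    out["event_time"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_reaction"] = IntegerVector(ev_r.begin(), ev_r.end());
  }
  return out;
}
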
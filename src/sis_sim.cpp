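// Event-driven SIS simulation with general (non-exponential) waiting times.
//
// Every infected node carries an absolute recovery time, every active
// directed edge an absolute transmission time; a min-heap over these times
// drives the dynamics. Entries are invalidated lazily: each node/edge keeps
// a version counter, bumped on every (de)activation, and stale heap entries
// are discarded on pop. Ties are broken by (time, kind with recovery first,
// entity id) so a run is reproducible bit-for-bit given the RNG stream.
//
// Two edge-activation mechanisms:
//   type-I : directed edge i<-j hosts a clock iff j is infected AND i is
//            susceptible; any state change at either end resets/kills it.
//   type-II: i<-j hosts a clock iff j is infected; it re-arms on every
//            firing and is untouched by the state of i.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF_T = std::numeric_limits<double>::infinity();

// waiting-time families, sampled by inverting the survival function
struct WtLaw {
  int family;       // 1 = weibull(shape, scale), 2 = beta_sigma1(gamma), 3 = exponential(rate)
  double p1, p2;
  double draw() const {
    double u = unif_rand();
    while (u <= 0.0 || u >= 1.0) u = unif_rand();
    switch (family) {
      case 1:  return p2 * std::pow(-std::log(u), 1.0 / p1);
      case 2:  return 1.0 - std::pow(u, 1.0 / p1);
      default: return -std::log(u) / p1;
    }
  }
};

struct Event {
  double t;
  int kind;   // 0 = recovery, 1 = transmission
  int id;     // node id or directed-edge id
  int ver;
};

struct EventLater {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    return a.id > b.id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sis_run_cpp")]]
List sis_run_cpp(int n,
                 IntegerVector edge_from, IntegerVector edge_to,
                 int mechanism,
                 int inf_family, NumericVector inf_pars,
                 int rec_family, NumericVector rec_pars,
                 IntegerVector seed_nodes,
                 double t_max,
                 NumericVector sample_times,
                 double max_events,
                 bool audit) {
  const int ne = edge_from.size();
  WtLaw inf_law{inf_family, inf_pars[0], inf_pars.size() > 1 ? inf_pars[1] : 0.0};
  WtLaw rec_law{rec_family, rec_pars[0], rec_pars.size() > 1 ? rec_pars[1] : 0.0};

  // directed edge 2e   : to[e] <- from[e]  (source from[e], target to[e])
  // directed edge 2e+1 : from[e] <- to[e]
  std::vector<int> src(2 * ne), tgt(2 * ne);
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) {
    src[2 * e] = edge_from[e];     tgt[2 * e] = edge_to[e];
    src[2 * e + 1] = edge_to[e];   tgt[2 * e + 1] = edge_from[e];
    ++deg[edge_from[e]]; ++deg[edge_to[e]];
  }
  // CSR of outgoing directed edges per node
  std::vector<int> ptr(n + 1, 0);
  for (int v = 0; v < n; ++v) ptr[v + 1] = ptr[v] + deg[v];
  std::vector<int> out_did(2 * ne);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int d = 0; d < 2 * ne; ++d) out_did[fill[src[d]]++] = d;
  }

  std::vector<int> status(n, 0);           // 0 = S, 1 = I
  std::vector<double> node_time(n, INF_T), edge_time(2 * ne, INF_T);
  std::vector<int> node_ver(n, 0), edge_ver(2 * ne, 0);
  std::vector<int> ever(n, 0);
  int infected = 0;

  std::priority_queue<Event, std::vector<Event>, EventLater> heap;

  auto activate_edge = [&](int d, double t) {
    edge_time[d] = t + inf_law.draw();
    ++edge_ver[d];
    heap.push({edge_time[d], 1, d, edge_ver[d]});
  };
  auto deactivate_edge = [&](int d) {
    if (edge_time[d] < INF_T) { edge_time[d] = INF_T; ++edge_ver[d]; }
  };
  auto infect_node = [&](int i, double t) {
    status[i] = 1; ever[i] = 1; ++infected;
    node_time[i] = t + rec_law.draw();
    ++node_ver[i];
    heap.push({node_time[i], 0, i, node_ver[i]});
  };

  // seeds: infected with age 0; their outgoing edges get fresh clocks
  for (int k = 0; k < seed_nodes.size(); ++k) infect_node(seed_nodes[k], 0.0);
  for (int k = 0; k < seed_nodes.size(); ++k) {
    int j = seed_nodes[k];
    for (int q = ptr[j]; q < ptr[j + 1]; ++q) {
      int d = out_did[q];
      if (mechanism == 2 || status[tgt[d]] == 0) activate_edge(d, 0.0);
    }
  }

  const int ns = sample_times.size();
  NumericVector density(ns);
  int sp = 0;
  double t = 0.0, extinct_time = NA_REAL;
  double n_events = 0.0;
  int audit_countdown = 0;
  bool hit_cap = false;

  auto flush_samples = [&](double up_to) {
    while (sp < ns && sample_times[sp] < up_to) {
      density[sp++] = static_cast<double>(infected) / n;
    }
  };

  while (!heap.empty()) {
    Event ev = heap.top(); heap.pop();
    bool valid = (ev.kind == 0) ? (ev.ver == node_ver[ev.id] && ev.t == node_time[ev.id])
                                : (ev.ver == edge_ver[ev.id] && ev.t == edge_time[ev.id]);
    if (!valid) continue;
    if (ev.t > t_max) { t = t_max; break; }
    flush_samples(ev.t);
    t = ev.t;
    n_events += 1.0;
    if (n_events > max_events) { hit_cap = true; break; }
    if (audit && ++audit_countdown == 1000) {
      audit_countdown = 0;
      // full state/heap consistency pass: the finite-clock predicate must
      // match the mechanism's active-edge rule exactly
      for (int d = 0; d < 2 * ne; ++d) {
        bool should = (status[src[d]] == 1) &&
                      (mechanism == 2 || status[tgt[d]] == 0);
        if (should != (edge_time[d] < INF_T)) {
          stop("internal error: edge state inconsistent with mechanism rule");
        }
      }
      for (int v = 0; v < n; ++v) {
        if ((status[v] == 1) != (node_time[v] < INF_T)) {
          stop("internal error: node state inconsistent with recovery clock");
        }
      }
    }

    if (ev.kind == 0) {
      // recovery of node j
      int j = ev.id;
      status[j] = 0; node_time[j] = INF_T; ++node_ver[j]; --infected;
      for (int q = ptr[j]; q < ptr[j + 1]; ++q) {
        int d = out_did[q];             // i <- j : source no longer infected
        deactivate_edge(d);
        if (mechanism == 1) {
          int d2 = d ^ 1;               // j <- i : j just became susceptible
          if (status[tgt[d]] == 1) activate_edge(d2, t);
        }
      }
      if (infected == 0) { extinct_time = t; break; }
    } else {
      // transmission along directed edge d : i <- j (j is infected)
      int d = ev.id;
      int i = tgt[d];
      if (mechanism == 1) {
        // i is susceptible or the clock would have been invalidated
        infect_node(i, t);
        for (int q = ptr[i]; q < ptr[i + 1]; ++q) {
          int dd = out_did[q];          // k <- i
          if (status[tgt[dd]] == 0) activate_edge(dd, t);
          deactivate_edge(dd ^ 1);      // i <- k : i no longer susceptible
        }
      } else {
        if (status[i] == 0) {
          infect_node(i, t);
          for (int q = ptr[i]; q < ptr[i + 1]; ++q) {
            activate_edge(out_did[q], t);   // all k <- i, regardless of k
          }
        }
        activate_edge(d, t);            // the used edge re-arms with age 0
      }
    }
  }
  flush_samples(t_max + 1.0);  // remaining samples see the final state
  if (R_IsNA(extinct_time) && infected == 0) extinct_time = t;

  return List::create(
    _["infected"] = density,
    _["extinct_time"] = extinct_time,
    _["n_events"] = n_events,
    _["ever_infected"] = IntegerVector(ever.begin(), ever.end()),
    _["hit_event_cap"] = hit_cap
  );
}
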
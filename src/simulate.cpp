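#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Fenwick (binary indexed) tree over per-neuron rates: O(log n) update,
// prefix-sum search for sampling a neuron proportional to its rate.
class RateTree {
  int n;
  std::vector<double> tree;  // 1-based
  std::vector<double> rate;
  long ops;
  // delta updates accumulate rounding error when rates of very different
  // magnitude share a node; rebuild exactly from the stored rates often
  // enough that the drift stays negligible
  void rebuild() {
    std::fill(tree.begin(), tree.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double d = rate[i];
      if (d != 0.0)
        for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
    }
  }
public:
  RateTree(int n_) : n(n_), tree(n_ + 1, 0.0), rate(n_, 0.0), ops(0) {}
  void set(int i, double r) {
    double d = r - rate[i];
    if (d == 0.0) return;
    rate[i] = r;
    if (++ops % 65536 == 0) { rebuild(); return; }
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
  }
  double get(int i) const { return rate[i]; }
  double total() const {
    double s = 0.0;
    for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  // smallest i such that prefix sum through i exceeds u
  int search(double u) const {
    int pos = 0;
    int mask = 1;
    while ((mask << 1) <= n) mask <<= 1;
    for (; mask > 0; mask >>= 1) {
      int next = pos + mask;
      if (next <= n && tree[next] < u) {
        u -= tree[next];
        pos = next;
      }
    }
    return pos;  // 0-based neuron index
  }
};

// Deterministic (scheduled) events.  type encodes the processing priority at
// equal times: PSP offsets first, then refractory expirations, then delayed
// PSP onsets, then ties broken by index.
struct DetEvent {
  double time;
  int type;  // 0 = psp offset, 1 = refractory end, 2 = psp onset
  int idx;   // synapse index (types 0, 2) or neuron index (type 1)
  bool operator>(const DetEvent& o) const {
    if (time != o.time) return time > o.time;
    if (type != o.type) return type > o.type;
    return idx > o.idx;
  }
};

typedef std::priority_queue<DetEvent, std::vector<DetEvent>,
                            std::greater<DetEvent> > EventQueue;

// Membrane potentials are capped at U_CAP when converted to rates: a neuron
// at u = 25 already fires within ~1e-13 s, so the cap is behaviorally
// equivalent to "fires immediately" while keeping the dynamic range of the
// summed rates within double precision (mixing rates ~1e45 with rates ~1e2
// in one prefix-sum tree silently absorbs the small ones).
static const double U_CAP = 25.0;

static inline double neuron_rate(double u, double tau) {
  if (u > U_CAP) u = U_CAP;
  double r = std::exp(u) / tau;
  if (!R_finite(r)) stop("non-finite firing rate");
  return r;
}

// Exact event-driven simulation of a network of stochastically firing point
// neurons with exponential intensity exp(u)/tau, rectangular PSPs and
// absolute refractoriness.  Between events all membrane potentials are
// constant, so the next spike is drawn competitively from the total rate and
// attributed to a neuron proportionally to its rate; memorylessness of the
// exponential makes redrawing after every event exact.
// [[Rcpp::export]]
List sim_spiking_cpp(NumericVector bias, NumericVector tau,
                     NumericVector refractory,
                     IntegerVector syn_pre, IntegerVector syn_post,
                     NumericVector syn_w, NumericVector syn_delay,
                     NumericVector syn_psp,
                     double t_end, double max_spikes,
                     IntegerVector initial_active) {
  const int n = bias.size();
  const int m = syn_pre.size();

  // outgoing adjacency
  std::vector<std::vector<int> > out(n);
  for (int s = 0; s < m; ++s) out[syn_pre[s]].push_back(s);

  std::vector<double> u(n);
  std::vector<bool> refr(n, false);
  for (int k = 0; k < n; ++k) u[k] = bias[k];

  // Per-synapse PSP expiry time.  The membrane potential depends on the
  // binary on/off state of each presynaptic neuron, so overlapping PSPs on
  // the same synapse renew the active window instead of stacking: an onset
  // while active only extends the expiry, and offset events that were
  // superseded by a later onset are skipped.
  std::vector<double> psp_end(m, R_NegInf);

  RateTree rates(n);
  EventQueue q;

  std::vector<double> sp_time;
  std::vector<int> sp_neuron;
  sp_time.reserve(4096);
  sp_neuron.reserve(4096);

  // Commit a spike of neuron k at time t: record, enter refractoriness,
  // schedule PSP onsets/offsets on all outgoing synapses.
  // Immediate (zero-delay) onsets are applied in place.
  std::vector<int> touched;
  touched.reserve(64);

  double t = 0.0;

  // Apply a PSP onset on synapse s at time `now`; returns the postsynaptic
  // index when the membrane potential changed, -1 when the synapse was
  // already active (window renewed only).
  auto apply_onset = [&](int s, double now) -> int {
    double e = now + syn_psp[s];
    if (psp_end[s] > now) {
      if (e > psp_end[s]) psp_end[s] = e;
      return -1;
    }
    psp_end[s] = e;
    u[syn_post[s]] += syn_w[s];
    return syn_post[s];
  };

  // virtual spikes at t = 0- for the initial active set
  for (int ii = 0; ii < initial_active.size(); ++ii) {
    int k = initial_active[ii];
    sp_time.push_back(0.0);
    sp_neuron.push_back(k);
    refr[k] = true;
    q.push(DetEvent{refractory[k], 1, k});
    for (size_t j = 0; j < out[k].size(); ++j) {
      int s = out[k][j];
      if (syn_delay[s] <= 0.0) {
        apply_onset(s, 0.0);
      } else {
        q.push(DetEvent{syn_delay[s], 2, s});
      }
      q.push(DetEvent{syn_delay[s] + syn_psp[s], 0, s});
    }
  }

  for (int k = 0; k < n; ++k) {
    if (!R_finite(u[k])) stop("non-finite membrane potential");
    rates.set(k, refr[k] ? 0.0 : neuron_rate(u[k], tau[k]));
  }

  long n_spikes = (long)sp_time.size();

  while (t < t_end) {
    if (n_spikes >= max_spikes) break;
    double t_det = q.empty() ? R_PosInf : q.top().time;
    double R_tot = rates.total();
    double t_spike = R_PosInf;
    if (R_tot > 0.0) t_spike = t + exp_rand() / R_tot;

    if (t_spike < t_det && t_spike <= t_end) {
      // commit a spike
      int k = rates.search(unif_rand() * R_tot);
      if (k >= n) k = n - 1;  // numerical edge of the prefix search
      if (rates.get(k) <= 0.0) { t = t_spike; continue; }  // fp edge: redraw
      t = t_spike;
      sp_time.push_back(t);
      sp_neuron.push_back(k);
      ++n_spikes;
      refr[k] = true;
      rates.set(k, 0.0);
      q.push(DetEvent{t + refractory[k], 1, k});
      touched.clear();
      for (size_t j = 0; j < out[k].size(); ++j) {
        int s = out[k][j];
        if (syn_delay[s] <= 0.0) {
          int p = apply_onset(s, t);
          if (p >= 0) touched.push_back(p);
        } else {
          q.push(DetEvent{t + syn_delay[s], 2, s});
        }
        q.push(DetEvent{t + syn_delay[s] + syn_psp[s], 0, s});
      }
      for (size_t j = 0; j < touched.size(); ++j) {
        int p = touched[j];
        if (!R_finite(u[p])) stop("non-finite membrane potential");
        if (!refr[p]) rates.set(p, neuron_rate(u[p], tau[p]));
      }
    } else if (t_det <= t_end) {
      // process every scheduled event at exactly this time, then redraw
      t = t_det;
      touched.clear();
      while (!q.empty() && q.top().time == t_det) {
        DetEvent ev = q.top();
        q.pop();
        if (ev.type == 0) {          // PSP offset
          if (ev.time >= psp_end[ev.idx]) {  // not superseded by a renewal
            u[syn_post[ev.idx]] -= syn_w[ev.idx];
            psp_end[ev.idx] = R_NegInf;
            touched.push_back(syn_post[ev.idx]);
          }
        } else if (ev.type == 1) {   // refractory expiration
          refr[ev.idx] = false;
          touched.push_back(ev.idx);
        } else {                     // delayed PSP onset
          int p = apply_onset(ev.idx, ev.time);
          if (p >= 0) touched.push_back(p);
        }
      }
      for (size_t j = 0; j < touched.size(); ++j) {
        int p = touched[j];
        if (!R_finite(u[p])) stop("non-finite membrane potential");
        rates.set(p, refr[p] ? 0.0 : neuron_rate(u[p], tau[p]));
      }
    } else {
      break;  // nothing left before t_end
    }
  }

  return List::create(_["time"] = wrap(sp_time),
                      _["neuron"] = wrap(sp_neuron),
                      _["t_last"] = t);
}

static inline double sigmoid(double u) {
  if (u >= 0.0) return 1.0 / (1.0 + std::exp(-u));
  double e = std::exp(u);
  return e / (1.0 + e);
}

// Continuous-time Gibbs sampler (Boltzmann machine): unit k switches on at
// rate rho0*sigma(u_k) and off at rate rho0*sigma(-u_k), with u_k the bias
// plus weighted sum of active presynaptic units.  Exact event-driven
// simulation via competing exponential clocks.
// [[Rcpp::export]]
List sim_gibbs_cpp(NumericVector bias,
                   IntegerVector w_from, IntegerVector w_to, NumericVector w_val,
                   double rho0, double t_end, double max_flips,
                   IntegerVector initial_active) {
  const int n = bias.size();
  const int m = w_from.size();

  std::vector<std::vector<std::pair<int, double> > > out(n);
  for (int s = 0; s < m; ++s)
    out[w_from[s]].push_back(std::make_pair(w_to[s], w_val[s]));

  std::vector<double> u(n);
  std::vector<int> x(n, 0);
  for (int k = 0; k < n; ++k) u[k] = bias[k];
  for (int ii = 0; ii < initial_active.size(); ++ii) {
    int k = initial_active[ii];
    x[k] = 1;
    for (size_t j = 0; j < out[k].size(); ++j)
      u[out[k][j].first] += out[k][j].second;
  }

  RateTree rates(n);
  for (int k = 0; k < n; ++k)
    rates.set(k, rho0 * sigmoid(x[k] ? -u[k] : u[k]));

  std::vector<double> fl_time;
  std::vector<int> fl_unit;
  std::vector<int> fl_dir;
  fl_time.reserve(4096);

  double t = 0.0;
  long n_flips = 0;
  while (t < t_end && n_flips < max_flips) {
    double R_tot = rates.total();
    if (R_tot <= 0.0) break;
    t += exp_rand() / R_tot;
    if (t > t_end) break;
    int k = rates.search(unif_rand() * R_tot);
    if (k >= n) k = n - 1;
    int dir = x[k] ? -1 : 1;
    x[k] = 1 - x[k];
    fl_time.push_back(t);
    fl_unit.push_back(k);
    fl_dir.push_back(dir);
    ++n_flips;
    for (size_t j = 0; j < out[k].size(); ++j) {
      int p = out[k][j].first;
      u[p] += dir * out[k][j].second;
      if (!R_finite(u[p])) stop("non-finite unit potential");
      rates.set(p, rho0 * sigmoid(x[p] ? -u[p] : u[p]));
    }
    rates.set(k, rho0 * sigmoid(x[k] ? -u[k] : u[k]));
  }

  return List::create(_["time"] = wrap(fl_time),
                      _["unit"] = wrap(fl_unit),
                      _["dir"] = wrap(fl_dir),
                      _["t_last"] = t);
}

// Energy jumps along a sequence of single-unit state changes.  For a change
// of model unit k the jump is -dir * (b_k + sum_l W[k,l] x_l) with x the
// state of the other units at the change (diagonal of W is zero).  Changes
// of units outside the model (idx < 0) yield NA.
// [[Rcpp::export]]
NumericVector energy_jumps_cpp(IntegerVector idx, IntegerVector dir,
                               NumericVector b, NumericMatrix W,
                               IntegerVector initial_state) {
  const int n = b.size();
  const int nc = idx.size();
  std::vector<int> x(initial_state.begin(), initial_state.end());
  NumericVector de(nc);
  for (int i = 0; i < nc; ++i) {
    int k = idx[i];
    if (k < 0) { de[i] = NA_REAL; continue; }
    double u = b[k];
    for (int l = 0; l < n; ++l) if (x[l]) u += W(k, l);
    de[i] = -dir[i] * u;
    x[k] += dir[i];
  }
  return de;
}

// Number of satisfied clauses after each state change of a compiled SAT
// network, under currently-active readout semantics: a clause is satisfied
// iff at least one principal neuron matching one of its literals is active.
// var_of / val_of map each neuron to its Boolean variable and truth value
// (var_of < 0 for non-principal neurons).
// [[Rcpp::export]]
IntegerVector sat_count_trace_cpp(IntegerVector neuron, IntegerVector dir,
                                  IntegerVector var_of, IntegerVector val_of,
                                  int n_vars,
                                  IntegerMatrix cl_var, IntegerMatrix cl_val) {
  const int M = cl_var.nrow();
  const int K = cl_var.ncol();
  // literal id = 2*var + val -> clauses containing it
  std::vector<std::vector<int> > lit_clauses(2 * n_vars);
  for (int mC = 0; mC < M; ++mC)
    for (int j = 0; j < K; ++j) {
      if (cl_var(mC, j) < 0) continue;  // padding for k < K clauses
      lit_clauses[2 * cl_var(mC, j) + cl_val(mC, j)].push_back(mC);
    }

  std::vector<int> lit_active(2 * n_vars, 0);   // active neuron count per literal
  std::vector<int> sat_lits(M, 0);              // active literal count per clause
  int n_sat = 0;

  const int nc = neuron.size();
  IntegerVector count(nc);
  for (int i = 0; i < nc; ++i) {
    int k = neuron[i];
    int v = var_of[k];
    if (v >= 0) {
      int lit = 2 * v + val_of[k];
      int before = lit_active[lit];
      lit_active[lit] += dir[i];
      int after = lit_active[lit];
      if (before == 0 && after > 0) {
        for (size_t j = 0; j < lit_clauses[lit].size(); ++j) {
          int mC = lit_clauses[lit][j];
          if (sat_lits[mC]++ == 0) ++n_sat;
        }
      } else if (before > 0 && after == 0) {
        for (size_t j = 0; j < lit_clauses[lit].size(); ++j) {
          int mC = lit_clauses[lit][j];
          if (--sat_lits[mC] == 0) --n_sat;
        }
      }
    }
    count[i] = n_sat;
  }
  return count;
}

// Per-change count of WTA groups whose number of active members differs
// from one (undefined problem variables).  group_of maps neurons to group
// index (< 0 for ungrouped); returns the count after each change.
// [[Rcpp::export]]
IntegerVector undefined_groups_trace_cpp(IntegerVector neuron, IntegerVector dir,
                                         IntegerVector group_of, int n_groups,
                                         IntegerVector initial_active) {
  std::vector<int> gsize(n_groups, 0);
  for (int ii = 0; ii < initial_active.size(); ++ii) {
    int g = group_of[initial_active[ii]];
    if (g >= 0) ++gsize[g];
  }
  int n_undef = 0;
  for (int g = 0; g < n_groups; ++g) if (gsize[g] != 1) ++n_undef;

  const int nc = neuron.size();
  IntegerVector out(nc);
  for (int i = 0; i < nc; ++i) {
    int g = group_of[neuron[i]];
    if (g >= 0) {
      bool was = gsize[g] != 1;
      gsize[g] += dir[i];
      bool is = gsize[g] != 1;
      if (was && !is) --n_undef;
      else if (!was && is) ++n_undef;
    }
    out[i] = n_undef;
  }
  return out;
}
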
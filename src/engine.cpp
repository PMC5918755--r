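// Simulation engine: dyadic coordination-game society with two groups,
// exponential-smoothing belief learning, conformity-modulated learning
// rates based on a distance-weighted group norm, and enlightenment
// interventions. Designed for 1e7-interaction horizons on one core.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: PCG32 substreams seeded via splitmix64 from one master seed.
// Named substreams keep initialization, dyad sampling, the two groups'
// action draws and intervention draws statistically independent, so that
// e.g. changing the in-group prior cannot perturb cross-group dynamics.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform double in [0, 1)
  double runif() { return next() * (1.0 / 4294967296.0); }
  // uniform integer in [0, n)
  int below(int n) {
    // rejection-free for our purposes: n is tiny relative to 2^32
    return (int)(((uint64_t)next() * (uint64_t)n) >> 32);
  }
  double rnorm() {
    // Box-Muller, one value per call (the spare is discarded; init only)
    double u1 = runif(), u2 = runif();
    while (u1 <= 0.0) u1 = runif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

enum Stream { S_INIT_CROSS = 0, S_INIT_IN = 1, S_DYAD = 2,
              S_ACT_DOM = 3, S_ACT_SUB = 4, S_INTERV = 5, N_STREAMS = 6 };

static void seed_streams(Pcg32 *streams, uint64_t master_seed, uint64_t replication) {
  uint64_t x = master_seed ^ (0xA0761D6478BD642FULL * (replication + 1));
  for (int k = 0; k < N_STREAMS; ++k) {
    uint64_t a = splitmix64(x);
    uint64_t b = splitmix64(x);
    streams[k].seed(a, b ^ (uint64_t)k);
  }
}

// ---------------------------------------------------------------------------
// Group-norm state: sorted member beliefs with incremental maintenance.
// Total pairwise distance of the r-th smallest member is obtained from a
// running prefix sum, so a full norm evaluation is one O(n) pass and a
// single belief change costs one O(n) sorted-vector splice.
// ---------------------------------------------------------------------------

static const double DIST_EPS = 1e-12;

struct NormState {
  std::vector<double> sorted;  // member beliefs, ascending
  double total;                // sum of beliefs (refreshed periodically)
  int variant;                 // 0 inverse_pairwise_distance, 1 mean, 2 median
  long refresh_countdown;

  void build(const std::vector<double> &vals, int var) {
    sorted = vals;
    std::sort(sorted.begin(), sorted.end());
    variant = var;
    refresh_total();
  }
  void refresh_total() {
    total = 0.0;
    for (double v : sorted) total += v;
    refresh_countdown = 1 << 20;
  }
  void replace(double oldv, double newv) {
    std::vector<double>::iterator it =
      std::lower_bound(sorted.begin(), sorted.end(), oldv);
    sorted.erase(it);
    sorted.insert(std::lower_bound(sorted.begin(), sorted.end(), newv), newv);
    total += newv - oldv;
    if (--refresh_countdown <= 0) refresh_total();
  }
  // total absolute distance from member at sorted position r to all members
  double dist_at(int r) const {
    int n = (int)sorted.size();
    double prefix = 0.0;
    for (int k = 0; k < r; ++k) prefix += sorted[k];
    double x = sorted[r];
    return x * (2.0 * r + 1.0 - n) + total - 2.0 * prefix - x;
  }
  double norm() const {
    int n = (int)sorted.size();
    if (n == 1) return sorted[0];
    if (sorted[0] == sorted[n - 1]) return sorted[0]; // all equal: common value
    double wsum = 0.0, wxsum = 0.0;
    if (variant == 0) {
      double prefix = 0.0; // sum of sorted[0..r-1]
      for (int r = 0; r < n; ++r) {
        double x = sorted[r];
        double d = x * (2.0 * r + 1.0 - n) + total - 2.0 * prefix - x;
        prefix += x;
        if (d < DIST_EPS) d = DIST_EPS;
        double w = 1.0 / d;
        wsum += w;
        wxsum += w * x;
      }
    } else {
      double m;
      if (variant == 1) m = total / n;
      else m = (n % 2 == 1) ? sorted[n / 2]
                            : 0.5 * (sorted[n / 2 - 1] + sorted[n / 2]);
      for (int r = 0; r < n; ++r) {
        double w = 1.0 / (std::fabs(sorted[r] - m) + DIST_EPS);
        wsum += w;
        wxsum += w * sorted[r];
      }
    }
    return wxsum / wsum;
  }
  double mean() const { return total / (double)sorted.size(); }
  double mean_abs_dev_from(double center) const {
    double s = 0.0;
    for (double v : sorted) s += std::fabs(v - center);
    return s / (double)sorted.size();
  }
};

// ---------------------------------------------------------------------------
// Configuration unpacking
// ---------------------------------------------------------------------------

struct Prior {
  int family; // 0 uniform, 1 truncated_normal (rejection within (0,1))
  double p1, p2;
  double draw(Pcg32 &rng) const {
    if (family == 0) return p1 + (p2 - p1) * rng.runif();
    double v;
    do { v = p1 + p2 * rng.rnorm(); } while (v <= 0.0 || v >= 1.0);
    return v;
  }
};

struct EngineConfig {
  int nI, nJ;
  Prior prior_dom_out, prior_sub_out, prior_dom_in, prior_sub_in;
  int alpha_mode;      // 0 constant, 1 conformity
  double alpha_const;
  int norm_variant;    // 0 inv pairwise, 1 mean, 2 median
  int action_rule;     // 0 bernoulli, 1 threshold (>= 0.5)
  int intervention;    // 0 none, 1 instant, 2 gradual
  double t_enl;        // T_e
  double repl_interval;
  int baseline_mode;   // 0 frozen, 1 redraw
  bool replacement_learns;
  double horizon;
  double audit_interval; // 0 = off
};

static Prior as_prior(List p) {
  Prior pr;
  std::string fam = as<std::string>(p["family"]);
  pr.family = (fam == "uniform") ? 0 : 1;
  pr.p1 = as<double>(p["p1"]);
  pr.p2 = as<double>(p["p2"]);
  return pr;
}

static EngineConfig unpack(List cfg) {
  EngineConfig c;
  c.nI = as<int>(cfg["n_dominant"]);
  c.nJ = as<int>(cfg["n_subordinate"]);
  c.prior_dom_out = as_prior(cfg["prior_dominant_out"]);
  c.prior_sub_out = as_prior(cfg["prior_subordinate_out"]);
  c.prior_dom_in  = as_prior(cfg["prior_dominant_in"]);
  c.prior_sub_in  = as_prior(cfg["prior_subordinate_in"]);
  std::string am = as<std::string>(cfg["alpha_mode"]);
  c.alpha_mode = (am == "constant") ? 0 : 1;
  c.alpha_const = as<double>(cfg["alpha_constant"]);
  std::string nv = as<std::string>(cfg["norm_variant"]);
  c.norm_variant = (nv == "inverse_pairwise_distance") ? 0
                 : (nv == "distance_from_mean") ? 1 : 2;
  std::string ar = as<std::string>(cfg["action_rule"]);
  c.action_rule = (ar == "bernoulli") ? 0 : 1;
  std::string iv = as<std::string>(cfg["intervention_mode"]);
  c.intervention = (iv == "none") ? 0 : (iv == "instant_enlightenment") ? 1 : 2;
  c.t_enl = as<double>(cfg["t_enlightenment"]);
  c.repl_interval = as<double>(cfg["replacement_interval"]);
  std::string bm = as<std::string>(cfg["baseline_mode"]);
  c.baseline_mode = (bm == "frozen") ? 0 : 1;
  c.replacement_learns = as<bool>(cfg["replacement_learns"]);
  c.horizon = as<double>(cfg["horizon"]);
  c.audit_interval = as<double>(cfg["audit_interval"]);
  return c;
}

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------

struct Engine {
  EngineConfig c;
  int n;
  // bel[a][g]: agent a's belief toward group g (0 = dominant I, 1 = subordinate J)
  std::vector<double> belI, belJ;
  std::vector<char> frozen;
  // quad[obs][tgt]: sorted beliefs of observer-group members toward target group
  NormState quad[2][2];
  Pcg32 streams[N_STREAMS];
  double t;
  bool enlightened; // instant enlightenment already triggered

  int group_of(int a) const { return a < c.nI ? 0 : 1; }
  double get_belief(int a, int tgt) const { return tgt == 0 ? belI[a] : belJ[a]; }
  void set_belief(int a, int tgt, double v) {
    int g = group_of(a);
    double old = get_belief(a, tgt);
    if (tgt == 0) belI[a] = v; else belJ[a] = v;
    quad[g][tgt].replace(old, v);
  }

  void init(uint64_t master_seed, uint64_t replication) {
    n = c.nI + c.nJ;
    belI.assign(n, 0.0);
    belJ.assign(n, 0.0);
    frozen.assign(n, 0);
    seed_streams(streams, master_seed, replication);
    // cross-group beliefs from their own substream, dominant block first
    for (int i = 0; i < c.nI; ++i) belJ[i] = c.prior_dom_out.draw(streams[S_INIT_CROSS]);
    for (int j = c.nI; j < n; ++j) belI[j] = c.prior_sub_out.draw(streams[S_INIT_CROSS]);
    for (int i = 0; i < c.nI; ++i) belI[i] = c.prior_dom_in.draw(streams[S_INIT_IN]);
    for (int j = c.nI; j < n; ++j) belJ[j] = c.prior_sub_in.draw(streams[S_INIT_IN]);
    rebuild_quads();
    t = 0.0;
    enlightened = false;
  }

  void rebuild_quads() {
    std::vector<double> v;
    for (int obs = 0; obs < 2; ++obs) {
      int from = obs == 0 ? 0 : c.nI, to = obs == 0 ? c.nI : n;
      for (int tgt = 0; tgt < 2; ++tgt) {
        v.clear();
        for (int a = from; a < to; ++a) v.push_back(get_belief(a, tgt));
        quad[obs][tgt].build(v, c.norm_variant);
      }
    }
  }

  void audit_check() {
    for (int obs = 0; obs < 2; ++obs) {
      int from = obs == 0 ? 0 : c.nI, to = obs == 0 ? c.nI : n;
      for (int tgt = 0; tgt < 2; ++tgt) {
        std::vector<double> v;
        for (int a = from; a < to; ++a) v.push_back(get_belief(a, tgt));
        std::sort(v.begin(), v.end());
        const NormState &q = quad[obs][tgt];
        if (v.size() != q.sorted.size())
          stop("norm-state audit failed: size mismatch");
        for (size_t k = 0; k < v.size(); ++k)
          if (std::fabs(v[k] - q.sorted[k]) > 1e-9)
            stop("norm-state audit failed: incremental state diverged from scratch");
        NormState fresh;
        fresh.build(v, c.norm_variant);
        if (std::fabs(fresh.norm() - q.norm()) > 1e-9)
          stop("norm-state audit failed: norm value diverged");
      }
    }
  }

  // one dyadic interaction; optionally fills a 9-value trace buffer
  void step(double *trace_buf) {
    // unordered uniform dyad: ordered distinct pair, order irrelevant
    int a = streams[S_DYAD].below(n);
    int b = streams[S_DYAD].below(n - 1);
    if (b >= a) ++b;
    int ga = group_of(a), gb = group_of(b);
    double bel_a = get_belief(a, gb), bel_b = get_belief(b, ga);
    // actions drawn simultaneously from pre-interaction beliefs;
    // a uniform is consumed per participant regardless of action rule so
    // that rule variants stay on the same random sequence
    double ua = streams[ga == 0 ? S_ACT_DOM : S_ACT_SUB].runif();
    double ub = streams[gb == 0 ? S_ACT_DOM : S_ACT_SUB].runif();
    int act_a = c.action_rule == 0 ? (ua < bel_a) : (bel_a >= 0.5);
    int act_b = c.action_rule == 0 ? (ub < bel_b) : (bel_b >= 0.5);
    // learning rates from pre-interaction belief configuration
    double alpha_a, alpha_b;
    if (c.alpha_mode == 0) {
      alpha_a = alpha_b = c.alpha_const;
    } else {
      alpha_a = std::fabs(bel_a - quad[ga][gb].norm());
      alpha_b = std::fabs(bel_b - quad[gb][ga].norm());
    }
    double new_a = alpha_a * act_b + (1.0 - alpha_a) * bel_a;
    double new_b = alpha_b * act_a + (1.0 - alpha_b) * bel_b;
    if (!frozen[a]) set_belief(a, gb, new_a);
    if (!frozen[b]) set_belief(b, ga, new_b);
    t += 1.0;
    if (trace_buf) {
      trace_buf[0] = t;
      trace_buf[1] = a + 1;
      trace_buf[2] = b + 1;
      trace_buf[3] = act_a;
      trace_buf[4] = act_b;
      trace_buf[5] = alpha_a;
      trace_buf[6] = alpha_b;
      trace_buf[7] = frozen[a] ? bel_a : new_a;
      trace_buf[8] = frozen[b] ? bel_b : new_b;
    }
  }

  void enlighten_all() {
    for (int i = 0; i < c.nI; ++i) {
      double v = streams[S_INTERV].runif();
      set_belief(i, 0, v);
      set_belief(i, 1, v);
      if (c.baseline_mode == 0) frozen[i] = 1;
    }
  }

  // returns replacement event (agent index 1-based) or 0
  int apply_interventions() {
    if (c.intervention == 1 && t >= c.t_enl) {
      if (!enlightened) {
        enlighten_all();
        enlightened = true;
      } else if (c.baseline_mode == 1) {
        enlighten_all(); // fresh enlightened generation every period
      }
      // frozen mode: baselines cannot drift (updates are skipped), so the
      // per-period reset is a no-op and needs no work
      return 0;
    }
    if (c.intervention == 2 && t >= c.t_enl && t > 0.0 &&
        (long long)t % (long long)c.repl_interval == 0) {
      int i = streams[S_INTERV].below(c.nI);
      double v = streams[S_INTERV].runif();
      set_belief(i, 0, v);
      set_belief(i, 1, v);
      if (!c.replacement_learns) frozen[i] = 1;
      return i + 1;
    }
    return 0;
  }

  double mean_out(int obs) const { return quad[obs][1 - obs].mean(); }
  double mean_alpha(int obs) const {
    if (c.alpha_mode == 0) return c.alpha_const;
    const NormState &q = quad[obs][1 - obs];
    return q.mean_abs_dev_from(q.norm());
  }

  NumericMatrix state_matrix() const {
    NumericMatrix m(n, 3);
    for (int a = 0; a < n; ++a) {
      m(a, 0) = group_of(a) + 1; // 1 dominant, 2 subordinate
      m(a, 1) = belI[a];
      m(a, 2) = belJ[a];
    }
    return m;
  }
};

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_init_population(List cfg, double seed, double replication) {
  Engine e;
  e.c = unpack(cfg);
  e.init((uint64_t)seed, (uint64_t)replication);
  return e.state_matrix();
}

// Run one replication. checkpoint_times must be increasing and include 0.
// Returns trajectory, initial/final state, optional per-step trace and the
// gradual-replacement event log.
// [[Rcpp::export]]
List cpp_run_replication(List cfg, double seed, double replication,
                         NumericVector checkpoint_times, bool record_trace) {
  Engine e;
  e.c = unpack(cfg);
  e.init((uint64_t)seed, (uint64_t)replication);
  long long horizon = (long long)e.c.horizon;
  int ncp = checkpoint_times.size();
  NumericMatrix traj(ncp, 5);
  colnames(traj) = CharacterVector::create(
    "time", "mean_dominant_to_subordinate", "mean_subordinate_to_dominant",
    "mean_alpha_dominant", "mean_alpha_subordinate");
  int cp = 0;
  // t = 0 checkpoint before any interaction
  if (cp < ncp && checkpoint_times[cp] == 0.0) {
    traj(cp, 0) = 0.0;
    traj(cp, 1) = e.mean_out(0);
    traj(cp, 2) = e.mean_out(1);
    traj(cp, 3) = e.mean_alpha(0);
    traj(cp, 4) = e.mean_alpha(1);
    ++cp;
  }
  NumericMatrix init_state = e.state_matrix();
  NumericMatrix trace;
  if (record_trace) {
    trace = NumericMatrix((int)horizon, 9);
    colnames(trace) = CharacterVector::create(
      "time", "agent_a", "agent_b", "action_a", "action_b",
      "alpha_a", "alpha_b", "new_belief_a", "new_belief_b");
  }
  std::vector<double> event_times;
  std::vector<int> event_agents;
  long long audit_every = (long long)e.c.audit_interval;
  double trace_buf[9];
  for (long long s = 1; s <= horizon; ++s) {
    e.step(record_trace ? trace_buf : (double *)0);
    if (record_trace) {
      for (int j = 0; j < 9; ++j) trace((int)(s - 1), j) = trace_buf[j];
    }
    int ev = e.apply_interventions();
    if (ev > 0) {
      event_times.push_back(e.t);
      event_agents.push_back(ev);
    }
    if (audit_every > 0 && s % audit_every == 0) e.audit_check();
    if (cp < ncp && e.t >= checkpoint_times[cp]) {
      traj(cp, 0) = e.t;
      traj(cp, 1) = e.mean_out(0);
      traj(cp, 2) = e.mean_out(1);
      traj(cp, 3) = e.mean_alpha(0);
      traj(cp, 4) = e.mean_alpha(1);
      ++cp;
    }
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
    _["trajectory"] = traj,
    _["initial_state"] = init_state,
    _["final_state"] = e.state_matrix(),
    _["replacement_times"] = wrap(event_times),
    _["replacement_agents"] = wrap(event_agents));
  if (record_trace) out["trace"] = trace;
  return out;
}

// From-scratch group norm on an arbitrary belief vector (same code path as
// the engine's NormState, built fresh).
// [[Rcpp::export]]
double cpp_group_norm(NumericVector beliefs, std::string variant) {
  NormState ns;
  std::vector<double> v(beliefs.begin(), beliefs.end());
  int var = (variant == "inverse_pairwise_distance") ? 0
          : (variant == "distance_from_mean") ? 1 : 2;
  ns.build(v, var);
  return ns.norm();
}

// Incremental-maintenance audit: apply a sequence of single-member belief
// changes through the sorted-structure path and report the final member
// distances and norm, for comparison with an O(n^2) from-scratch oracle.
// [[Rcpp::export]]
List cpp_norm_incremental_audit(NumericVector beliefs, IntegerVector members,
                                NumericVector new_values, std::string variant) {
  NormState ns;
  std::vector<double> cur(beliefs.begin(), beliefs.end());
  int var = (variant == "inverse_pairwise_distance") ? 0
          : (variant == "distance_from_mean") ? 1 : 2;
  ns.build(cur, var);
  NumericVector norms(members.size());
  for (int k = 0; k < members.size(); ++k) {
    int i = members[k] - 1;
    ns.replace(cur[i], new_values[k]);
    cur[i] = new_values[k];
    norms[k] = ns.norm();
  }
  int n = (int)cur.size();
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    std::vector<double>::iterator it =
      std::lower_bound(ns.sorted.begin(), ns.sorted.end(), cur[i]);
    d[i] = ns.dist_at((int)(it - ns.sorted.begin()));
  }
  return List::create(_["distances"] = d, _["norm"] = ns.norm(),
                      _["norms_after_each"] = norms,
                      _["sorted"] = wrap(ns.sorted));
}
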
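// Clock-driven LIF network engine with homeostatic structural plasticity.
//
// Design notes:
//  * Exact exponential-Euler integration of the leak between grid points;
//    all synaptic events are delta pulses applied on the step grid, delayed
//    through a ring buffer of `delay` steps.
//  * Three independent PCG32 streams (background, stimulus, structural)
//    seeded from one master seed, so runs are bit-reproducible and the
//    background realization does not depend on whether a stimulus is on.
//  * Calcium traces are updated lazily (flushed at spikes, structural
//    updates, and run end) so the per-step cost is dominated by one Poisson
//    draw per neuron.
//  * E-E connectivity is held as per-neuron synapse multisets (out_syn /
//    in_syn, one entry per synapse, multapses as repeats); the dense count
//    matrix A[i][j] is only materialized for snapshots.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

struct pcg32 {
  uint64_t state = 0u, inc = 1u;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  inline uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  inline double unif() {  // uniform in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  inline uint32_t bounded(uint32_t n) {  // uniform integer in [0, n)
    uint32_t threshold = (-n) % n;
    for (;;) {
      uint32_t r = next();
      if (r >= threshold) return r % n;
    }
  }
};

// Poisson sampler for a fixed mean: alias method (Vose) over the truncated
// pmf, so each draw costs one RNG call and two table lookups.
struct poisson_table {
  std::vector<double> prob;   // acceptance probability per column
  std::vector<int> alias;
  int K = 1;
  void init(double lambda) {
    std::vector<double> pmf;
    if (lambda <= 0.0) {
      pmf.assign(1, 1.0);
    } else {
      double p = std::exp(-lambda), c = p;
      pmf.push_back(p);
      int k = 0;
      while (c < 1.0 - 1e-13 && k < 512) {
        ++k;
        p *= lambda / k;
        c += p;
        pmf.push_back(p);
      }
      pmf.back() += 1.0 - c;  // fold the tail into the last bin
    }
    K = (int)pmf.size();
    prob.assign(K, 0.0);
    alias.assign(K, 0);
    std::vector<double> scaled(K);
    std::vector<int> small, large;
    for (int k = 0; k < K; ++k) {
      scaled[k] = pmf[k] * K;
      (scaled[k] < 1.0 ? small : large).push_back(k);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  inline int draw(pcg32& rng) const {
    double u = rng.unif() * K;
    int k = (int)u;
    if (k >= K) k = K - 1;
    return (u - k) < prob[k] ? k : alias[k];
  }
};

// ------------------------------------------------------- rewiring core ----

struct rewire_events {
  bool record = false;
  std::vector<double> t;
  std::vector<int> type;  // 1 = form, -1 = delete
  std::vector<int> pre, post;
  void push(double time, int ty, int p, int q) {  // p, q are 0-based internally
    if (!record) return;
    t.push_back(time); type.push_back(ty); pre.push_back(p + 1); post.push_back(q + 1);
  }
};

// Remove one entry equal to `val` from vec (swap-remove); hard error if absent.
static inline void remove_one(std::vector<int>& vec, int val) {
  for (size_t k = 0; k < vec.size(); ++k) {
    if (vec[k] == val) {
      vec[k] = vec.back();
      vec.pop_back();
      return;
    }
  }
  stop("internal error: synapse multisets out of sync");
}

// One structural-plasticity rewiring step.
//  1) deletion of the axonal deficit (per neuron, neurons in random order),
//  2) deletion of the dendritic deficit (recomputed, random order),
//  3) formation by uniform random pairing of the free-element pools,
//     self-pairings redrawn (skipped when only self-pairings remain).
static void rewire_step(int n_E,
                        std::vector<std::vector<int>>& out_syn,
                        std::vector<std::vector<int>>& in_syn,
                        const std::vector<double>& z_axon,
                        const std::vector<double>& z_dend,
                        pcg32& rng, double t_now, rewire_events& ev) {
  std::vector<int> order(n_E);
  for (int i = 0; i < n_E; ++i) order[i] = i;
  // axonal deficits
  for (int i = n_E - 1; i > 0; --i) std::swap(order[i], order[rng.bounded(i + 1)]);
  for (int oi = 0; oi < n_E; ++oi) {
    int j = order[oi];
    int deficit = (int)out_syn[j].size() - (int)std::floor(z_axon[j]);
    while (deficit > 0 && !out_syn[j].empty()) {
      uint32_t k = rng.bounded((uint32_t)out_syn[j].size());
      int i_post = out_syn[j][k];
      out_syn[j][k] = out_syn[j].back();
      out_syn[j].pop_back();
      remove_one(in_syn[i_post], j);
      ev.push(t_now, -1, j, i_post);
      --deficit;
    }
  }
  // dendritic deficits (axonal deletions above may already have resolved some)
  for (int i = n_E - 1; i > 0; --i) std::swap(order[i], order[rng.bounded(i + 1)]);
  for (int oi = 0; oi < n_E; ++oi) {
    int i = order[oi];
    int deficit = (int)in_syn[i].size() - (int)std::floor(z_dend[i]);
    while (deficit > 0 && !in_syn[i].empty()) {
      uint32_t k = rng.bounded((uint32_t)in_syn[i].size());
      int j_pre = in_syn[i][k];
      in_syn[i][k] = in_syn[i].back();
      in_syn[i].pop_back();
      remove_one(out_syn[j_pre], i);
      ev.push(t_now, -1, j_pre, i);
      --deficit;
    }
  }
  // formation: pool free elements (floor(z) - bound, positive part)
  std::vector<int> ax, de;
  for (int j = 0; j < n_E; ++j) {
    int f = (int)std::floor(z_axon[j]) - (int)out_syn[j].size();
    for (int k = 0; k < f; ++k) ax.push_back(j);
    f = (int)std::floor(z_dend[j]) - (int)in_syn[j].size();
    for (int k = 0; k < f; ++k) de.push_back(j);
  }
  while (!ax.empty() && !de.empty()) {
    uint32_t ka = rng.bounded((uint32_t)ax.size());
    uint32_t kd = rng.bounded((uint32_t)de.size());
    int j = ax[ka], i = de[kd];
    if (j == i) {
      // redraw, unless only self-pairings remain
      bool stuck = true;
      for (size_t q = 0; q < ax.size() && stuck; ++q) if (ax[q] != j) stuck = false;
      for (size_t q = 0; q < de.size() && stuck; ++q) if (de[q] != j) stuck = false;
      if (stuck) break;
      continue;
    }
    out_syn[j].push_back(i);
    in_syn[i].push_back(j);
    ev.push(t_now, 1, j, i);
    ax[ka] = ax.back(); ax.pop_back();
    de[kd] = de.back(); de.pop_back();
  }
}

// ------------------------------------------------------------- helpers ----

static std::vector<std::vector<int>> adjacency(const IntegerVector& pre,
                                               const IntegerVector& post,
                                               int n_pre) {
  std::vector<std::vector<int>> out((size_t)n_pre);
  int m = pre.size();
  for (int k = 0; k < m; ++k) {
    int j = pre[k] - 1, i = post[k] - 1;
    if (j < 0 || j >= n_pre) stop("presynaptic id out of range");
    out[j].push_back(i);
  }
  return out;
}

// Aggregate the synapse multiset into (post, pre, count) triplets, 1-based.
static List triplets(const std::vector<std::vector<int>>& out_syn, double t_now) {
  std::vector<int> ti, tj, tn;
  std::vector<int> buf;
  int n_E = (int)out_syn.size();
  for (int j = 0; j < n_E; ++j) {
    buf = out_syn[j];
    std::sort(buf.begin(), buf.end());
    size_t k = 0;
    while (k < buf.size()) {
      size_t k2 = k;
      while (k2 < buf.size() && buf[k2] == buf[k]) ++k2;
      ti.push_back(buf[k] + 1);
      tj.push_back(j + 1);
      tn.push_back((int)(k2 - k));
      k = k2;
    }
  }
  return List::create(_["t"] = t_now, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["n"] = wrap(tn));
}

struct pois_segment {
  std::vector<int> mask;   // 0-based global ids
  double weight = 0.0;
  poisson_table tab;
  double count = 0.0;      // diagnostic: total events delivered
};

// ------------------------------------------------------------ cpp_run ----

// [[Rcpp::export]]
List cpp_run(List network, List state, List params, List segments, List opts) {
  // --- unpack network -----------------------------------------------------
  const int n_E = as<int>(network["n_E"]);
  const int n_I = as<int>(network["n_I"]);
  const int n = n_E + n_I;

  std::vector<std::vector<int>> out_syn =
    adjacency(network["ee_pre"], network["ee_post"], n_E);
  std::vector<std::vector<int>> e2i =
    adjacency(network["ei_pre"], network["ei_post"], n_E);
  std::vector<std::vector<int>> i2e =
    adjacency(network["ie_pre"], network["ie_post"], n_I);
  std::vector<std::vector<int>> i2i =
    adjacency(network["ii_pre"], network["ii_post"], n_I);

  // --- unpack parameters --------------------------------------------------
  const double dt = as<double>(params["dt_ms"]);           // ms
  const double tau_m = as<double>(params["tau_m_ms"]);     // ms
  const double V_theta = as<double>(params["v_theta_mv"]);
  const double V_reset = as<double>(params["v_reset_mv"]);
  const double t_ref = as<double>(params["t_ref_ms"]);
  const double delay = as<double>(params["delay_ms"]);
  const double J = as<double>(params["j_mv"]);
  const double g = as<double>(params["g"]);
  const double nu_ext = as<double>(params["nu_ext_hz"]);
  const double tau_ca = as<double>(params["tau_ca_s"]);    // s
  const double beta_ca = as<double>(params["beta_ca"]);
  const double nu_g = as<double>(params["nu_g"]);          // elements / s
  const double eps_ca = as<double>(params["eps_ca"]);
  const double dt_struct = as<double>(params["dt_struct_s"]);

  const bool hsp = as<bool>(opts["hsp"]);
  const bool thresholds = as<bool>(opts["thresholds"]);
  const bool record_spikes = as<bool>(opts["record_spikes"]);
  const bool diag_counts = as<bool>(opts["diag_input_counts"]);
  const double duration_s = as<double>(opts["duration_s"]);
  const double window_s = as<double>(opts["record_window_s"]);
  const double gamma_stride_s = as<double>(opts["gamma_stride_s"]);
  const uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  rewire_events ev;
  ev.record = as<bool>(opts["record_rewire_events"]);

  if (dt <= 0) stop("dt must be positive");
  if (delay + 1e-9 < dt) stop("synaptic delay must be at least one step (dt <= delay)");

  const int delay_steps = (int)std::lround(delay / dt);
  const int ref_steps = (int)std::lround(t_ref / dt);
  const int ring_len = delay_steps + 1;
  const double decay = std::exp(-dt / tau_m);
  const double one_m_decay = 1.0 - decay;
  const double ca_decay = std::exp(-dt / (tau_ca * 1000.0));
  const int struct_every = std::max(1, (int)std::lround(dt_struct * 1000.0 / dt));
  const int win_every = window_s > 0 ? (int)std::lround(window_s * 1000.0 / dt) : 0;
  const int gamma_every = gamma_stride_s > 0 ?
    (int)std::lround(gamma_stride_s * 1000.0 / dt) : 0;

  // --- unpack state -------------------------------------------------------
  std::vector<double> V = as<std::vector<double>>(state["v_mv"]);
  std::vector<double> ref_ms = as<std::vector<double>>(state["ref_ms"]);
  std::vector<double> Ca = as<std::vector<double>>(state["ca"]);
  std::vector<double> z_axon = as<std::vector<double>>(state["z_axon"]);
  std::vector<double> z_dend = as<std::vector<double>>(state["z_dend"]);
  const double t0_s = as<double>(state["t0_s"]);
  if ((int)V.size() != n || (int)Ca.size() != n_E)
    stop("state dimensions do not match the network");

  std::vector<std::vector<int>> in_syn((size_t)n_E);
  if (hsp) {
    for (int j = 0; j < n_E; ++j)
      for (int i : out_syn[j]) in_syn[i].push_back(j);
  }

  std::vector<int> ref_steps_left(n);
  for (int i = 0; i < n; ++i)
    ref_steps_left[i] = (int)std::lround(std::max(0.0, ref_ms[i]) / dt);

  const int64_t s0 = (int64_t)std::llround(t0_s * 1000.0 / dt);
  const int64_t n_steps = (int64_t)std::llround(duration_s * 1000.0 / dt);
  std::vector<int64_t> ca_step((size_t)n_E, s0);

  // --- RNG streams --------------------------------------------------------
  pcg32 rng_bg, rng_stim, rng_struct;
  rng_bg.seed(seed, 54u);
  rng_stim.seed(seed, 198u);
  rng_struct.seed(seed, 1022u);

  poisson_table bg_tab;
  bg_tab.init(nu_ext * dt / 1000.0);

  // --- segments -----------------------------------------------------------
  const int n_seg = segments.size();
  std::vector<pois_segment> pseg(n_seg);
  std::vector<double> seg_dvm(n_seg, 0.0);
  std::vector<int> seg_is_pois(n_seg, 0);
  std::vector<std::vector<int>> seg_mask(n_seg);
  // boundary events: (step, seg index, +1 on / -1 off), processed in order
  struct bevent { int64_t step; int seg; int on; };
  std::vector<bevent> bevents;
  for (int sgi = 0; sgi < n_seg; ++sgi) {
    List sg = segments[sgi];
    std::string type = as<std::string>(sg["type"]);
    IntegerVector m = sg["mask"];
    for (int k = 0; k < m.size(); ++k) {
      int id = m[k] - 1;
      if (id < 0 || id >= n) stop("drive mask references an invalid neuron id");
      seg_mask[sgi].push_back(id);
    }
    int64_t a = (int64_t)std::llround(as<double>(sg["start_s"]) * 1000.0 / dt);
    int64_t b = (int64_t)std::llround(as<double>(sg["stop_s"]) * 1000.0 / dt);
    a = std::max(a, s0); b = std::min(b, s0 + n_steps);
    if (type == "poisson") {
      seg_is_pois[sgi] = 1;
      pseg[sgi].mask = seg_mask[sgi];
      pseg[sgi].weight = as<double>(sg["weight_mv"]);
      pseg[sgi].tab.init(as<double>(sg["rate_hz"]) * dt / 1000.0);
    } else if (type == "dc") {
      seg_dvm[sgi] = as<double>(sg["dvm_mv"]);
    } else {
      stop("unknown drive segment type: " + type);
    }
    if (a < b) {
      bevents.push_back({a, sgi, 1});
      bevents.push_back({b, sgi, -1});
    }
  }
  std::sort(bevents.begin(), bevents.end(),
            [](const bevent& x, const bevent& y) {
              return x.step < y.step || (x.step == y.step && x.on > y.on);
            });

  std::vector<double> dc_amp(n, 0.0);
  std::vector<int> active_pois;  // segment indices, activation order

  // --- recording ----------------------------------------------------------
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> win_counter(n, 0);
  std::vector<int> win_counts;       // row-major: window x neuron
  std::vector<double> win_t0;
  std::vector<int> part;             // 0-based group label per E neuron
  int n_groups = 0;
  if (gamma_every > 0) {
    IntegerVector p = opts["part"];
    if (p.size() != n_E) stop("partition must label every excitatory neuron");
    part.resize(n_E);
    for (int i = 0; i < n_E; ++i) {
      part[i] = p[i] - 1;
      if (part[i] < 0) stop("partition labels must be positive integers");
      n_groups = std::max(n_groups, part[i] + 1);
    }
  }
  std::vector<double> gamma_t;
  std::vector<double> gamma_sums;    // row-major: record x (G*G), S[q][p]
  NumericVector snap_req = opts["snapshot_s"];
  std::vector<int64_t> snap_steps;
  for (int k = 0; k < snap_req.size(); ++k)
    snap_steps.push_back((int64_t)std::llround(snap_req[k] * 1000.0 / dt));
  std::sort(snap_steps.begin(), snap_steps.end());
  List snapshots;

  std::vector<double> bg_counts;
  if (diag_counts) bg_counts.assign(n, 0.0);

  auto record_gamma = [&](double t_now) {
    if (gamma_every <= 0) return;
    std::vector<double> S((size_t)n_groups * n_groups, 0.0);
    for (int j = 0; j < n_E; ++j) {
      const int pj = part[j];
      for (int i : out_syn[j]) S[(size_t)part[i] * n_groups + pj] += 1.0;
    }
    gamma_t.push_back(t_now);
    gamma_sums.insert(gamma_sums.end(), S.begin(), S.end());
  };

  auto flush_ca = [&](int i, int64_t to_step) {
    int64_t ds = to_step - ca_step[i];
    if (ds > 0) {
      Ca[i] *= std::pow(ca_decay, (double)ds);
      ca_step[i] = to_step;
    }
  };

  std::vector<double> ring((size_t)ring_len * n, 0.0);

  record_gamma(t0_s);
  size_t snap_ptr = 0;
  while (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] <= s0) {
    if (snap_steps[snap_ptr] == s0)
      snapshots.push_back(triplets(out_syn, t0_s));
    ++snap_ptr;
  }

  size_t bev_ptr = 0;
  std::vector<int> spiked;
  spiked.reserve(256);

  // --- main loop ----------------------------------------------------------
  for (int64_t s = 0; s < n_steps; ++s) {
    const int64_t abs_step = s0 + s;
    // segment on/off switches effective at the start of this step
    while (bev_ptr < bevents.size() && bevents[bev_ptr].step <= abs_step) {
      const bevent& be = bevents[bev_ptr];
      if (be.step == abs_step) {
        if (seg_is_pois[be.seg]) {
          if (be.on > 0) active_pois.push_back(be.seg);
          else active_pois.erase(std::remove(active_pois.begin(),
                                             active_pois.end(), be.seg),
                                 active_pois.end());
        } else {
          for (int id : seg_mask[be.seg]) dc_amp[id] += be.on * seg_dvm[be.seg];
        }
      }
      ++bev_ptr;
    }

    double* ring_now = &ring[(size_t)(abs_step % ring_len) * n];

    // leak + delayed recurrent + DC + background
    for (int i = 0; i < n; ++i) {
      if (ref_steps_left[i] > 0) {
        --ref_steps_left[i];
        V[i] = V_reset;
        ring_now[i] = 0.0;
        int k = bg_tab.draw(rng_bg);  // keep the background stream aligned
        if (diag_counts) bg_counts[i] += k;
        continue;
      }
      double v = V[i] * decay + dc_amp[i] * one_m_decay + ring_now[i];
      ring_now[i] = 0.0;
      int k = bg_tab.draw(rng_bg);
      if (k) v += k * J;
      if (diag_counts) bg_counts[i] += k;
      V[i] = v;
    }

    // stimulus Poisson segments
    for (int sgi : active_pois) {
      pois_segment& ps = pseg[sgi];
      for (int id : ps.mask) {
        int k = ps.tab.draw(rng_stim);
        if (ref_steps_left[id] > 0) continue;  // input discarded while refractory
        if (k) {
          V[id] += k * ps.weight;
          ps.count += k;
        }
      }
    }

    // threshold crossing, reset, spike delivery
    if (thresholds) {
      spiked.clear();
      for (int i = 0; i < n; ++i) {
        if (ref_steps_left[i] == 0 && V[i] >= V_theta) spiked.push_back(i);
      }
      if (!spiked.empty()) {
        const double t_spk = (abs_step + 1) * dt / 1000.0;
        double* ring_fut = &ring[(size_t)((abs_step + delay_steps) % ring_len) * n];
        for (int i : spiked) {
          V[i] = V_reset;
          ref_steps_left[i] = ref_steps;
          ++win_counter[i];
          if (record_spikes) { spike_id.push_back(i + 1); spike_t.push_back(t_spk); }
          if (i < n_E) {
            flush_ca(i, abs_step + 1);
            Ca[i] += beta_ca;
            for (int q : out_syn[i]) ring_fut[q] += J;
            for (int q : e2i[i]) ring_fut[n_E + q] += J;
          } else {
            const int ii = i - n_E;
            const double w = -g * J;
            for (int q : i2e[ii]) ring_fut[q] += w;
            for (int q : i2i[ii]) ring_fut[n_E + q] += w;
          }
        }
      }
    }

    // structural plasticity update
    if (hsp && ((abs_step + 1) % struct_every == 0)) {
      const double t_now = (abs_step + 1) * dt / 1000.0;
      for (int i = 0; i < n_E; ++i) {
        flush_ca(i, abs_step + 1);
        double dz = nu_g * (1.0 - Ca[i] / eps_ca) * dt_struct;
        z_axon[i] = std::max(0.0, z_axon[i] + dz);
        z_dend[i] = std::max(0.0, z_dend[i] + dz);
      }
      rewire_step(n_E, out_syn, in_syn, z_axon, z_dend, rng_struct, t_now, ev);
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential at t = %f s (parameter blow-up?)",
               t_now);
    }

    // recordings aligned to the absolute step grid
    if (win_every > 0 && ((abs_step + 1) % win_every == 0)) {
      win_counts.insert(win_counts.end(), win_counter.begin(), win_counter.end());
      win_t0.push_back(((abs_step + 1) * dt / 1000.0) - window_s);
      std::fill(win_counter.begin(), win_counter.end(), 0);
    }
    if (gamma_every > 0 && ((abs_step + 1) % gamma_every == 0))
      record_gamma((abs_step + 1) * dt / 1000.0);
    while (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] == abs_step + 1) {
      snapshots.push_back(triplets(out_syn, (abs_step + 1) * dt / 1000.0));
      ++snap_ptr;
    }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // --- final state --------------------------------------------------------
  const int64_t s_end = s0 + n_steps;
  for (int i = 0; i < n_E; ++i) flush_ca(i, s_end);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(V[i]))
      stop("non-finite membrane potential at end of run (parameter blow-up?)");
    ref_ms[i] = ref_steps_left[i] * dt;
  }

  std::vector<int> ee_pre_out, ee_post_out;
  for (int j = 0; j < n_E; ++j)
    for (int i : out_syn[j]) { ee_pre_out.push_back(j + 1); ee_post_out.push_back(i + 1); }

  int n_win = (int)win_t0.size();
  IntegerMatrix win_mat(n_win, n);
  for (int w = 0; w < n_win; ++w)
    for (int i = 0; i < n; ++i) win_mat(w, i) = win_counts[(size_t)w * n + i];

  int n_gam = (int)gamma_t.size();
  NumericMatrix gam_mat(n_gam, n_groups * n_groups);
  for (int w = 0; w < n_gam; ++w)
    for (int k = 0; k < n_groups * n_groups; ++k)
      gam_mat(w, k) = gamma_sums[(size_t)w * n_groups * n_groups + k];

  List out = List::create(
    _["state"] = List::create(
      _["v_mv"] = wrap(V), _["ref_ms"] = wrap(ref_ms), _["ca"] = wrap(Ca),
      _["z_axon"] = wrap(z_axon), _["z_dend"] = wrap(z_dend),
      _["t0_s"] = s_end * dt / 1000.0),
    _["ee_pre"] = wrap(ee_pre_out),
    _["ee_post"] = wrap(ee_post_out),
    _["spike_id"] = wrap(spike_id),
    _["spike_t"] = wrap(spike_t),
    _["win_counts"] = win_mat,
    _["win_t0"] = wrap(win_t0),
    _["gamma_t"] = wrap(gamma_t),
    _["gamma_sums"] = gam_mat,
    _["n_groups"] = n_groups,
    _["snapshots"] = snapshots);
  if (diag_counts) {
    std::vector<double> seg_counts(n_seg, 0.0);
    for (int sgi = 0; sgi < n_seg; ++sgi) seg_counts[sgi] = pseg[sgi].count;
    out["bg_counts"] = wrap(bg_counts);
    out["seg_counts"] = wrap(seg_counts);
  }
  if (ev.record) {
    out["events"] = List::create(
      _["time_s"] = wrap(ev.t), _["type"] = wrap(ev.type),
      _["pre"] = wrap(ev.pre), _["post"] = wrap(ev.post));
  }
  return out;
}

// ------------------------------------------------- exposed rewiring op ----

// [[Rcpp::export]]
List cpp_rewire(int n_E, IntegerVector ee_pre, IntegerVector ee_post,
                NumericVector z_axon, NumericVector z_dend, double seed) {
  std::vector<std::vector<int>> out_syn = adjacency(ee_pre, ee_post, n_E);
  std::vector<std::vector<int>> in_syn((size_t)n_E);
  for (int j = 0; j < n_E; ++j)
    for (int i : out_syn[j]) {
      if (i < 0 || i >= n_E) stop("postsynaptic id out of range");
      if (i == j) stop("autapse in input connectivity");
      in_syn[i].push_back(j);
    }
  std::vector<double> za = as<std::vector<double>>(z_axon);
  std::vector<double> zd = as<std::vector<double>>(z_dend);
  if ((int)za.size() != n_E || (int)zd.size() != n_E)
    stop("element counts must have length n_E");
  for (int j = 0; j < n_E; ++j)
    if (za[j] < 0 || zd[j] < 0) stop("element counts must be non-negative");
  pcg32 rng;
  rng.seed((uint64_t)seed, 1022u);
  rewire_events ev;
  ev.record = true;
  rewire_step(n_E, out_syn, in_syn, za, zd, rng, 0.0, ev);
  std::vector<int> pre_out, post_out;
  for (int j = 0; j < n_E; ++j)
    for (int i : out_syn[j]) { pre_out.push_back(j + 1); post_out.push_back(i + 1); }
  return List::create(
    _["ee_pre"] = wrap(pre_out), _["ee_post"] = wrap(post_out),
    _["events"] = List::create(
      _["type"] = wrap(ev.type), _["pre"] = wrap(ev.pre), _["post"] = wrap(ev.post)));
}
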
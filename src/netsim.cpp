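// Core integrator for conductance-based quadratic integrate-and-fire (QIF)
// column networks generating interneuron gamma (ING) oscillations.
//
// Membrane dynamics (per neuron, SI units):
//   C dV/dt = p2 V^2 + p1 V + p0 + I_syn + sigma_n * eta(t) + I_pulse
// where eta is unit-variance 1/f (pink) noise, private to each neuron, and
// I_syn sums exponential-kernel synaptic currents driving V toward the
// excitatory / inhibitory reversal potentials; with the default "volt"
// normalization the conductance-times-driving-force product is taken
// literally in SI units:
//   I_chan = g(t) * (V_rev - V) * 1 V^-1
// (alternative normalizations divide by |V_e - V_reset| or by each kernel's
// own |V_rev - V_reset|).  Spikes are registered at the V_thresh crossing,
// V is reset, and the spike is delivered to each synaptic target after the
// projection delay (integer multiple of dt).  Time stepping is forward
// Euler at dt = 0.1 ms, with the synapse-linearized part integrated by the
// exponential-Euler rule when stiff.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x9E3779B97f4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  // approximately standard normal (Irwin-Hall sum of 4 uniforms); after the
  // pink-noise filter the output is indistinguishable from Gaussian for the
  // purposes of a noise drive
  inline double white() {
    return (unif() + unif() + unif() + unif() - 2.0) * 1.7320508075688772;
  }
  inline int poisson(double lambda, double expmlam) {
    // Knuth product method; lambda is small (events per 0.1 ms bin)
    int k = 0;
    double p = 1.0;
    do { ++k; p *= unif(); } while (p > expmlam);
    (void)lambda;
    return k - 1;
  }
};

// -------------------------------------------------- streaming pink noise --

// Paul Kellett's 7-pole 1/f filter: six one-pole lowpass sections plus a
// direct and a one-sample-delayed white term.  Accurate 1/f spectrum from
// ~1e-4 of the sampling rate up to Nyquist; output rescaled to exactly unit
// stationary standard deviation (closed-form variance of the linear filter).
static const double PK_P[6] = {0.99886, 0.99332, 0.96900, 0.86650, 0.55000, -0.7616};
static const double PK_Q[6] = {0.0555179, 0.0750759, 0.1538520, 0.3104856, 0.5329522, -0.0168980};
static const double PK_D = 0.5362;
static const double PK_E = 0.115926;

static double pink_stationary_sd() {
  double v = PK_D * PK_D + PK_E * PK_E;
  for (int j = 0; j < 6; ++j) {
    for (int k = 0; k < 6; ++k)
      v += PK_Q[j] * PK_Q[k] / (1.0 - PK_P[j] * PK_P[k]);
    v += 2.0 * PK_D * PK_Q[j];
    v += 2.0 * PK_E * PK_P[j] * PK_Q[j];
  }
  return std::sqrt(v);
}

struct PinkState {
  double b[6];
  double wprev;
  void init() { for (int i = 0; i < 6; ++i) b[i] = 0.0; wprev = 0.0; }
  inline double next(Xoshiro &rng, double inv_sd) {
    double w = rng.white();
    double y = PK_D * w + PK_E * wprev;
    for (int i = 0; i < 6; ++i) {
      b[i] = PK_P[i] * b[i] + PK_Q[i] * w;
      y += b[i];
    }
    wprev = w;
    return y * inv_sd;
  }
};

// [[Rcpp::export(name = ".pink_noise_cpp")]]
NumericVector pink_noise_cpp(int n, double seed, double stream) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, 0x504B4E00ULL + (uint64_t)stream);
  PinkState st;
  st.init();
  double inv_sd = 1.0 / pink_stationary_sd();
  // burn-in so the slow poles reach stationarity
  for (int i = 0; i < 20000; ++i) st.next(rng, inv_sd);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st.next(rng, inv_sd);
  return out;
}

// ------------------------------------------------------------ simulator ---

struct Group {           // one (population, pool)
  int pop;               // population index
  int pool;              // 0 = exc, 1 = inh
  int n;
  int g0;                // global neuron offset
};

struct Chan {            // one synaptic channel (projection or drive) into a group
  int target_group;
  int src_group;         // -1 for afferent drive
  std::string source_key;
  bool inhib;            // kernel type
  double w;              // weight (A)
  int delay_steps;       // >= 1 for projections; 0 for drive
  std::vector<double> g1, g2;    // kernel states per target neuron (A)
  std::vector<double> ring;      // pending spike counts, (delay+1) x n
  std::vector<int> adj_ptr, adj_idx;  // CSR source neuron -> local target idx
  double acc;                    // per-ms summed-current accumulator
  std::vector<double> sig;       // recorded 1 kHz current (sum over pool)
  bool record;
  bool current_type;             // deliver kernel as injected current (no reversal factor)
};

struct Pulse {
  int pop;
  double amp;            // A
  long onset_step;
  long off_step;
};

struct DriveCfg {
  double rate0[2];       // base rate per pool (events/s)
  double sigma_f;
  std::vector<double> flicker;   // values in [-1,1]
  double flicker_step;           // s
};

class NetSim {
public:
  double dt;
  uint64_t seed;       // structural seed (connectivity)
  uint64_t sim_seed;   // realization seed (noise, Poisson)
  long step_now;
  int n_pops, n_neurons;

  // per population parameters
  std::vector<double> p0, p1, p2, Ve, Vi, Vth, Vreset, sigma_n, C_e, C_i;
  std::vector<std::string> pop_ids;
  std::vector<DriveCfg> drives;

  std::vector<Group> groups;            // 2 per pop: exc then inh
  std::vector<Chan> chans;
  std::vector<std::vector<int>> chans_into;   // group -> channel indices
  std::vector<std::vector<int>> chans_from;   // group -> channel indices

  std::vector<double> V;                // per neuron
  std::vector<Xoshiro> rng_noise, rng_poiss;
  std::vector<PinkState> pink;
  double pink_inv_sd;

  std::vector<Pulse> pulses;

  // outputs
  std::vector<double> sp_time;          // s
  std::vector<int> sp_pop, sp_pool, sp_idx;
  std::vector<std::vector<double>> rate_counts;  // per group, per ms spike count

  // decay factors
  double dec_e, dec_i1, dec_i2, chi1, chi2;
  double tau_e, tau_i1, tau_i2;
  int norm_mode;            // 0 = volt (divide by 1 V), 1 = common |Ve-Vreset|, 2 = per-reversal
  bool drive_as_current;    // afferent drive injected as current, not conductance

  // scratch
  std::vector<double> Isyn, Gsyn;

  NetSim(List cfg) {
    dt = as<double>(cfg["dt"]);
    seed = (uint64_t)as<double>(cfg["seed"]);
    sim_seed = cfg.containsElementNamed("sim_seed")
                   ? (uint64_t)as<double>(cfg["sim_seed"]) : seed;
    step_now = 0;
    std::string nm = cfg.containsElementNamed("syn_norm")
        ? as<std::string>(cfg["syn_norm"]) : "volt";
    norm_mode = (nm == "per_reversal") ? 2 : (nm == "common" ? 1 : 0);
    drive_as_current = cfg.containsElementNamed("drive_type")
        ? (as<std::string>(cfg["drive_type"]) == "current") : false;

    List pops = cfg["populations"];
    n_pops = pops.size();
    List syn = cfg["synapses"];
    tau_e = as<double>(syn["tau_e"]);
    tau_i1 = as<double>(syn["tau_i1"]);
    tau_i2 = as<double>(syn["tau_i2"]);
    chi1 = as<double>(syn["chi1"]);
    chi2 = as<double>(syn["chi2"]);
    double w_e = as<double>(syn["w_e"]);
    double w_i = as<double>(syn["w_i"]);
    dec_e = std::exp(-dt / tau_e);
    dec_i1 = std::exp(-dt / tau_i1);
    dec_i2 = std::exp(-dt / tau_i2);

    n_neurons = 0;
    for (int p = 0; p < n_pops; ++p) {
      List pp = pops[p];
      pop_ids.push_back(as<std::string>(pp["id"]));
      int ne = as<int>(pp["n_exc"]), ni = as<int>(pp["n_inh"]);
      double cs = as<double>(pp["cm_specific"]);
      C_e.push_back(cs * as<double>(pp["area_exc"]));
      C_i.push_back(cs * as<double>(pp["area_inh"]));
      p0.push_back(as<double>(pp["p0"]));
      p1.push_back(as<double>(pp["p1"]));
      p2.push_back(as<double>(pp["p2"]));
      Ve.push_back(as<double>(pp["V_e"]));
      Vi.push_back(as<double>(pp["V_i"]));
      Vth.push_back(as<double>(pp["V_thresh"]));
      Vreset.push_back(as<double>(pp["V_reset"]));
      sigma_n.push_back(as<double>(pp["sigma_n"]));
      Group ge; ge.pop = p; ge.pool = 0; ge.n = ne; ge.g0 = n_neurons;
      groups.push_back(ge);
      n_neurons += ne;
      Group gi; gi.pop = p; gi.pool = 1; gi.n = ni; gi.g0 = n_neurons;
      groups.push_back(gi);
      n_neurons += ni;
    }

    V.assign(n_neurons, 0.0);
    rng_noise.resize(n_neurons);
    rng_poiss.resize(n_neurons);
    pink.resize(n_neurons);
    pink_inv_sd = 1.0 / pink_stationary_sd();
    for (int i = 0; i < n_neurons; ++i) {
      rng_noise[i].seed(sim_seed, 0x100000ULL + (uint64_t)i);
      rng_poiss[i].seed(sim_seed, 0x200000ULL + (uint64_t)i);
      pink[i].init();
      // short burn-in keeps stationary statistics from the first step
      for (int k = 0; k < 5000; ++k) pink[i].next(rng_noise[i], pink_inv_sd);
    }
    for (int g = 0; g < (int)groups.size(); ++g) {
      for (int i = 0; i < groups[g].n; ++i) V[groups[g].g0 + i] = Vreset[groups[g].pop];
    }

    chans_into.assign(groups.size(), std::vector<int>());
    chans_from.assign(groups.size(), std::vector<int>());

    // afferent drive channels (zero delay, excitatory kernel, weight w_e)
    drives.resize(n_pops);
    List drv = cfg["drives"];
    CharacterVector dnames = drv.names();
    for (int k = 0; k < drv.size(); ++k) {
      std::string id = as<std::string>(dnames[k]);
      int p = pop_index(id);
      List d = drv[k];
      drives[p].rate0[0] = as<double>(d["rate_exc"]);
      drives[p].rate0[1] = as<double>(d["rate_inh"]);
      drives[p].sigma_f = as<double>(d["sigma_f"]);
      drives[p].flicker = as<std::vector<double>>(d["flicker"]);
      drives[p].flicker_step = as<double>(d["flicker_step"]);
      for (int pool = 0; pool < 2; ++pool) {
        if (drives[p].rate0[pool] <= 0) continue;
        Chan c;
        c.target_group = 2 * p + pool;
        c.src_group = -1;
        c.source_key = "drive";
        c.inhib = false;
        c.w = w_e;
        c.delay_steps = 0;
        c.g1.assign(groups[c.target_group].n, 0.0);
        c.acc = 0.0;
        c.record = (pool == 0);
        c.current_type = drive_as_current;
        chans.push_back(c);
      }
    }

    // projections
    List projs = cfg["projections"];
    for (int k = 0; k < projs.size(); ++k) {
      List pr = projs[k];
      std::string sp = as<std::string>(pr["source_pop"]);
      std::string tp = as<std::string>(pr["target_pop"]);
      int spool = as<std::string>(pr["source_pool"]) == "inh" ? 1 : 0;
      int tpool = as<std::string>(pr["target_pool"]) == "inh" ? 1 : 0;
      double prob = as<double>(pr["prob"]);
      double delay = as<double>(pr["delay"]);
      bool inhib = as<std::string>(pr["kind"]) == "inhibitory";
      Chan c;
      c.src_group = 2 * pop_index(sp) + spool;
      c.target_group = 2 * pop_index(tp) + tpool;
      c.inhib = inhib;
      c.w = inhib ? w_i : w_e;
      c.delay_steps = (int)std::lround(delay / dt);
      if (c.delay_steps < 1)
        stop("projection delay must round to at least one integration step");
      int ns = groups[c.src_group].n, nt = groups[c.target_group].n;
      c.g1.assign(nt, 0.0);
      if (inhib) c.g2.assign(nt, 0.0);
      c.ring.assign((size_t)(c.delay_steps + 1) * nt, 0.0);
      c.acc = 0.0;
      c.record = (tpool == 0);
      c.current_type = false;
      c.source_key = sp + "_" + (spool ? "inh" : "exc");
      // Bernoulli adjacency from a dedicated stream (reproducible per projection)
      Xoshiro crng;
      crng.seed(seed, 0x300000ULL + (uint64_t)k);
      c.adj_ptr.assign(ns + 1, 0);
      for (int s = 0; s < ns; ++s) {
        for (int t = 0; t < nt; ++t) {
          if (c.src_group == c.target_group && s == t) continue;  // no autapses
          if (crng.unif() < prob) c.adj_idx.push_back(t);
        }
        c.adj_ptr[s + 1] = (int)c.adj_idx.size();
      }
      chans.push_back(c);
    }

    for (int ci = 0; ci < (int)chans.size(); ++ci) {
      chans_into[chans[ci].target_group].push_back(ci);
      if (chans[ci].src_group >= 0) chans_from[chans[ci].src_group].push_back(ci);
    }
    rate_counts.assign(groups.size(), std::vector<double>());
    Isyn.clear();
  }

  int pop_index(const std::string &id) {
    for (int p = 0; p < n_pops; ++p) if (pop_ids[p] == id) return p;
    stop("unknown population id '%s'", id.c_str());
    return -1;
  }

  void add_pulse(std::string pop, double amp, double onset, double dur) {
    Pulse pu;
    pu.pop = pop_index(pop);
    pu.amp = amp;
    pu.onset_step = (long)std::lround(onset / dt);
    pu.off_step = pu.onset_step + (long)std::max(1.0, std::round(dur / dt));
    if (pu.onset_step < step_now)
      stop("pulse onset %.4f s lies before current simulation time", onset);
    pulses.push_back(pu);
  }

  double drive_rate(int p, int pool, double t) {
    const DriveCfg &d = drives[p];
    double r = d.rate0[pool];
    if (r <= 0) return 0.0;
    if (!d.flicker.empty() && d.sigma_f > 0) {
      size_t idx = (size_t)(t / d.flicker_step);
      if (idx >= d.flicker.size()) idx = d.flicker.size() - 1;
      r *= (1.0 + d.sigma_f * d.flicker[idx]);
    }
    return r > 0 ? r : 0.0;
  }

  void step_ms(int n_ms) {
    int steps_per_ms = (int)std::lround(0.001 / dt);
    std::vector<double> Ipulse(n_pops, 0.0);
    std::vector<double> lam(2 * n_pops, 0.0), expml(2 * n_pops, 1.0);

    for (int ms = 0; ms < n_ms; ++ms) {
      double t_ms = step_now * dt;
      // afferent rates are piecewise constant over >= 1 ms (flicker step 10 ms)
      for (int p = 0; p < n_pops; ++p)
        for (int pool = 0; pool < 2; ++pool) {
          double l = drive_rate(p, pool, t_ms) * dt;
          lam[2 * p + pool] = l;
          expml[2 * p + pool] = std::exp(-l);
        }
      // per-ms spike counters
      for (size_t g = 0; g < groups.size(); ++g) rate_counts[g].push_back(0.0);

      for (int sub = 0; sub < steps_per_ms; ++sub) {
        double t = step_now * dt;
        // pulses
        std::fill(Ipulse.begin(), Ipulse.end(), 0.0);
        for (size_t q = 0; q < pulses.size(); ++q)
          if (step_now >= pulses[q].onset_step && step_now < pulses[q].off_step)
            Ipulse[pulses[q].pop] += pulses[q].amp;

        // kernel decay + delayed spike delivery
        for (size_t ci = 0; ci < chans.size(); ++ci) {
          Chan &c = chans[ci];
          int nt = (int)c.g1.size();
          if (c.inhib) {
            for (int i = 0; i < nt; ++i) { c.g1[i] *= dec_i1; c.g2[i] *= dec_i2; }
          } else {
            for (int i = 0; i < nt; ++i) c.g1[i] *= dec_e;
          }
          if (c.delay_steps > 0) {
            int slot = (int)(step_now % (c.delay_steps + 1));
            double *row = &c.ring[(size_t)slot * nt];
            if (c.inhib) {
              double a1 = c.w * chi1, a2 = c.w * chi2;
              for (int i = 0; i < nt; ++i) {
                if (row[i] != 0.0) { c.g1[i] += a1 * row[i]; c.g2[i] += a2 * row[i]; row[i] = 0.0; }
              }
            } else {
              for (int i = 0; i < nt; ++i) {
                if (row[i] != 0.0) { c.g1[i] += c.w * row[i]; row[i] = 0.0; }
              }
            }
          } else if (c.src_group == -1) {
            // afferent drive: Poisson event counts per neuron per bin
            const Group &tg = groups[c.target_group];
            double l = lam[2 * tg.pop + tg.pool];
            if (l > 0) {
              double em = expml[2 * tg.pop + tg.pool];
              for (int i = 0; i < nt; ++i) {
                int k = rng_poiss[tg.g0 + i].poisson(l, em);
                if (k > 0) c.g1[i] += c.w * k;
              }
            }
          }
        }

        // Membrane update, group by group.  The synaptic term is linear in
        // V (effective conductance G = sum g/|Vrev - Vreset| pulling toward
        // the reversal potentials); during population bursts G*dt/C can
        // exceed 1, so the linear part is integrated with the exponential
        // Euler rule (exact for frozen G), which reduces to forward Euler
        // in the non-stiff limit and never overshoots the reversals.
        for (size_t g = 0; g < groups.size(); ++g) {
          const Group &gr = groups[g];
          int n = gr.n, g0 = gr.g0, p = gr.pop;
          if ((int)Isyn.size() < n) { Isyn.assign(n, 0.0); Gsyn.assign(n, 0.0); }
          std::fill(Isyn.begin(), Isyn.begin() + n, 0.0);   // sum g*vrev/|..|
          std::fill(Gsyn.begin(), Gsyn.begin() + n, 0.0);   // sum g/|..|
          for (size_t kk = 0; kk < chans_into[g].size(); ++kk) {
            Chan &c = chans[chans_into[g][kk]];
            double vrev = c.inhib ? Vi[p] : Ve[p];
            double inv = 1.0;  // "volt": g*(Vrev-V) taken literally in SI
            if (norm_mode == 2 && c.inhib) inv = 1.0 / std::fabs(Vi[p] - Vreset[p]);
            else if (norm_mode >= 1) inv = 1.0 / std::fabs(Ve[p] - Vreset[p]);
            double accl = 0.0;
            if (c.current_type) {
              for (int i = 0; i < n; ++i) {
                Isyn[i] += c.g1[i];
                accl += c.g1[i];
              }
            } else if (c.inhib) {
              for (int i = 0; i < n; ++i) {
                double gc = (c.g1[i] + c.g2[i]) * inv;
                Gsyn[i] += gc; Isyn[i] += gc * vrev;
                accl += gc * (vrev - V[g0 + i]);
              }
            } else {
              for (int i = 0; i < n; ++i) {
                double gc = c.g1[i] * inv;
                Gsyn[i] += gc; Isyn[i] += gc * vrev;
                accl += gc * (vrev - V[g0 + i]);
              }
            }
            c.acc += accl;
          }
          double Cm = gr.pool ? C_i[p] : C_e[p];
          double Cinv = 1.0 / Cm;
          double a2 = p2[p], a1 = p1[p], a0 = p0[p];
          double sn = sigma_n[p], Ip = Ipulse[p];
          double vth = Vth[p], vre = Vreset[p];
          for (int i = 0; i < n; ++i) {
            int gi = g0 + i;
            double v = V[gi];
            double eta = (sn > 0) ? pink[gi].next(rng_noise[gi], pink_inv_sd) : 0.0;
            double A = (a2 * v + a1) * v + a0 + Isyn[i] + sn * eta + Ip;
            double B = Gsyn[i];
            double bdt = B * dt * Cinv;
            if (bdt < 0.01) {
              v += dt * (A - B * v) * Cinv;
            } else {
              double vinf = A / B;
              v = vinf + (v - vinf) * std::exp(-bdt);
            }
            if (v >= vth) {
              sp_time.push_back(t + dt);
              sp_pop.push_back(p);
              sp_pool.push_back(gr.pool);
              sp_idx.push_back(i);
              rate_counts[g].back() += 1.0;
              v = vre;
              // deliver to all outgoing channels
              const std::vector<int> &out = chans_from[g];
              for (size_t oc = 0; oc < out.size(); ++oc) {
                Chan &c = chans[out[oc]];
                int nt = (int)c.g1.size();
                int slot = (int)((step_now + c.delay_steps) % (c.delay_steps + 1));
                double *row = &c.ring[(size_t)slot * nt];
                for (int e = c.adj_ptr[i]; e < c.adj_ptr[i + 1]; ++e)
                  row[c.adj_idx[e]] += 1.0;
              }
            }
            if (v > 0.0 || v < -1.0 || !std::isfinite(v))
              stop("membrane potential diverged (pop %s, %s neuron %d, t = %.4f s)",
                   pop_ids[p].c_str(), gr.pool ? "inh" : "exc", i + 1, t);
            V[gi] = v;
          }
        }
        ++step_now;
      }

      // close the 1 ms bin: store averaged channel currents
      for (size_t ci = 0; ci < chans.size(); ++ci) {
        Chan &c = chans[ci];
        if (c.record) c.sig.push_back(c.acc / steps_per_ms);
        c.acc = 0.0;
      }
    }
  }

  List signals() {
    List out;
    for (int p = 0; p < n_pops; ++p) {
      int ge = 2 * p, gi = 2 * p + 1;
      int nb = (int)rate_counts[ge].size();
      NumericVector er(nb), ir(nb);
      for (int i = 0; i < nb; ++i) {
        er[i] = rate_counts[ge][i] / (groups[ge].n * 0.001);
        ir[i] = rate_counts[gi][i] / (groups[gi].n * 0.001);
      }
      List cur;
      for (size_t ci = 0; ci < chans.size(); ++ci) {
        const Chan &c = chans[ci];
        if (c.record && c.target_group == ge)
          cur[c.source_key] = NumericVector(c.sig.begin(), c.sig.end());
      }
      out[pop_ids[p]] = List::create(_["exc_rate"] = er, _["inh_rate"] = ir,
                                     _["currents"] = cur);
    }
    return out;
  }

  List spikes() {
    CharacterVector pop(sp_pop.size());
    CharacterVector pool(sp_pop.size());
    for (size_t i = 0; i < sp_pop.size(); ++i) {
      pop[i] = pop_ids[sp_pop[i]];
      pool[i] = sp_pool[i] ? "inh" : "exc";
    }
    return List::create(_["time"] = NumericVector(sp_time.begin(), sp_time.end()),
                        _["population"] = pop, _["pool"] = pool,
                        _["neuron"] = IntegerVector(sp_idx.begin(), sp_idx.end()));
  }

  List adjacency() {
    List out;
    int k = 0;
    for (size_t ci = 0; ci < chans.size(); ++ci) {
      const Chan &c = chans[ci];
      if (c.src_group < 0) continue;
      const Group &sg = groups[c.src_group];
      const Group &tg = groups[c.target_group];
      out[std::to_string(++k)] = List::create(
          _["source"] = pop_ids[sg.pop] + std::string("_") + (sg.pool ? "inh" : "exc"),
          _["target"] = pop_ids[tg.pop] + std::string("_") + (tg.pool ? "inh" : "exc"),
          _["n_synapses"] = (int)c.adj_idx.size(),
          _["adj_ptr"] = IntegerVector(c.adj_ptr.begin(), c.adj_ptr.end()),
          _["adj_idx"] = IntegerVector(c.adj_idx.begin(), c.adj_idx.end()));
    }
    return out;
  }
};

// ------------------------------------------------------------ interface ---

// [[Rcpp::export(name = ".sim_create")]]
SEXP sim_create(List cfg) {
  XPtr<NetSim> ptr(new NetSim(cfg), true);
  return ptr;
}

// [[Rcpp::export(name = ".sim_step")]]
void sim_step(SEXP xp, int n_ms) {
  XPtr<NetSim> ptr(xp);
  ptr->step_ms(n_ms);
}

// [[Rcpp::export(name = ".sim_add_pulse")]]
void sim_add_pulse(SEXP xp, std::string pop, double amp, double onset, double dur) {
  XPtr<NetSim> ptr(xp);
  ptr->add_pulse(pop, amp, onset, dur);
}

// [[Rcpp::export(name = ".sim_time")]]
double sim_time(SEXP xp) {
  XPtr<NetSim> ptr(xp);
  return ptr->step_now * ptr->dt;
}

// [[Rcpp::export(name = ".sim_signals")]]
List sim_signals(SEXP xp) {
  XPtr<NetSim> ptr(xp);
  return ptr->signals();
}

// [[Rcpp::export(name = ".sim_spikes")]]
List sim_spikes(SEXP xp) {
  XPtr<NetSim> ptr(xp);
  return ptr->spikes();
}

// [[Rcpp::export(name = ".sim_adjacency")]]
List sim_adjacency(SEXP xp) {
  XPtr<NetSim> ptr(xp);
  return ptr->adjacency();
}

// [[Rcpp::export(name = ".sim_signal_tail")]]
NumericVector sim_signal_tail(SEXP xp, std::string pop, std::string component,
                              int n_ms) {
  XPtr<NetSim> ptr(xp);
  int p = ptr->pop_index(pop);
  const std::vector<double> *src = nullptr;
  if (component == "exc_rate" || component == "inh_rate") {
    int g = 2 * p + (component == "inh_rate" ? 1 : 0);
    static std::vector<double> rates;  // scratch
    const std::vector<double> &cnt = ptr->rate_counts[g];
    int n = (int)cnt.size();
    int k = std::min(n_ms, n);
    NumericVector out(k);
    double scale = 1.0 / (ptr->groups[g].n * 0.001);
    for (int i = 0; i < k; ++i) out[i] = cnt[n - k + i] * scale;
    return out;
  }
  for (size_t ci = 0; ci < ptr->chans.size(); ++ci) {
    const Chan &c = ptr->chans[ci];
    if (c.record && c.target_group == 2 * p && c.source_key == component) {
      src = &c.sig;
      break;
    }
  }
  if (!src) stop("unknown signal component '%s'", component.c_str());
  int n = (int)src->size();
  int k = std::min(n_ms, n);
  NumericVector out(k);
  for (int i = 0; i < k; ++i) out[i] = (*src)[n - k + i];
  return out;
}

// [[Rcpp::export(name = ".sim_membrane")]]
NumericVector sim_membrane(SEXP xp) {
  XPtr<NetSim> ptr(xp);
  return NumericVector(ptr->V.begin(), ptr->V.end());
}
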
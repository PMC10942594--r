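// Closed-loop septo-hippocampal network integrator.
//
// Unit conventions used throughout the compiled core:
//   time ms, voltage mV, conductance uS, current nA, capacitance nF,
//   calcium mol/L, Kuramoto rates rad/s (converted at the clock boundary).
// With these units nA/nF = mV/ms, so the membrane equation needs no extra
// conversion factors.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// gating-rate primitives
// ---------------------------------------------------------------------------

// x / (1 - exp(-x/k)), analytic limit k as x -> 0
static inline double vtrap_up(double x, double k) {
  double r = x / k;
  if (std::fabs(r) < 1e-7) return k * (1.0 + r / 2.0);
  return x / (1.0 - std::exp(-r));
}

// x / (exp(x/k) - 1), analytic limit k as x -> 0
static inline double vtrap_down(double x, double k) {
  double r = x / k;
  if (std::fabs(r) < 1e-7) return k * (1.0 - r / 2.0);
  return x / (std::exp(r) - 1.0);
}

// rates in ms^-1, voltages in mV.  Pyramidal/granule (Traub-Miles lineage
// with Pospischil-style Ca and M currents), interneurons Wang-Buzsaki.
struct GateRates { double a, b; };

// Gate time constants: tau = 1/(phi (a+b)) with the temperature-like factor
// phi = 5 where the source formalisms carry one (Wang-Buzsaki interneuron
// gates, the calcium-gated CAN gate), i.e. tau = 0.2/(a+b) for those gates,
// and phi = 1 for the pyramidal-cell voltage gates (Traub-Miles/Pospischil).
static const double PHI_INH = 5.0;
static const double PHI_CAN = 5.0;


static inline GateRates exc_n(double v)  { return { 0.032 * vtrap_up(v + 40.0, 5.0), 0.5 * std::exp(-(v + 45.0) / 40.0) }; }
static inline GateRates exc_m(double v)  { return { 0.32  * vtrap_up(v + 42.0, 4.0), 0.28 * vtrap_down(v + 15.0, 5.0) }; }
static inline GateRates exc_h(double v)  { return { 0.128 * std::exp(-(v + 38.0) / 18.0), 4.0 / (1.0 + std::exp(-(v + 15.0) / 5.0)) }; }
static inline GateRates exc_mca(double v){ return { 0.055 * vtrap_down(-(v + 27.0), 3.8), 0.94 * std::exp(-(v + 75.0) / 17.0) }; }
static inline GateRates exc_hca(double v){ return { 0.000457 * std::exp(-(v + 13.0) / 50.0), 0.0065 / (1.0 + std::exp(-(v + 15.0) / 28.0)) }; }
static inline double exc_pinf(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
// tau_max = 1 s (returned in ms)
static inline double exc_taup(double v)  { return 1000.0 / (3.3 * std::exp((v + 35.0) / 20.0) + std::exp(-(v + 35.0) / 20.0)); }
// CAN gate rates depend on intracellular calcium (uM): quadratic activation
// law alpha = beta (Ca / Ca_c)^2 with half-activation Ca_c = 0.5 uM
static inline GateRates exc_can_raw(double ca) {
  double b = 2e-4 * std::exp(1.4);
  double r = ca / 0.5;
  return { b * r * r, b };
}
static inline GateRates exc_can(double ca) {
  GateRates r = exc_can_raw(ca); r.a *= PHI_CAN; r.b *= PHI_CAN; return r;
}

static inline GateRates inh_n_raw(double v) { return { 0.01 * vtrap_up(v + 34.0, 10.0), 0.125 * std::exp(-(v + 44.0) / 80.0) }; }
static inline GateRates inh_m_raw(double v) { return { 0.1  * vtrap_up(v + 35.0, 10.0), 4.0 * std::exp(-(v + 60.0) / 18.0) }; }
static inline GateRates inh_h_raw(double v) { return { 0.07 * std::exp(-(v + 58.0) / 20.0), 1.0 / (1.0 + std::exp(-0.1 * (v + 28.0))) }; }
static inline GateRates phi_scale(GateRates r, double phi) { r.a *= phi; r.b *= phi; return r; }
static inline GateRates inh_n(double v) { return phi_scale(inh_n_raw(v), PHI_INH); }
static inline GateRates inh_m(double v) { return phi_scale(inh_m_raw(v), PHI_INH); }
static inline GateRates inh_h(double v) { return phi_scale(inh_h_raw(v), PHI_INH); }

static inline double gate_inf(const GateRates& r) { return r.a / (r.a + r.b); }
static inline double gate_tau(const GateRates& r) { return 1.0 / (r.a + r.b); }

// exponential-Euler update of one gate
static inline double gate_step(double x, const GateRates& r, double dt) {
  double xinf = gate_inf(r), tau = gate_tau(r);
  double xn = xinf + (x - xinf) * std::exp(-dt / tau);
  if (xn < 0.0) xn = 0.0; else if (xn > 1.0) xn = 1.0;
  return xn;
}

// ---------------------------------------------------------------------------
// per-run gating lookup tables (x_inf and exp(-dt/tau) sampled on a fine
// voltage grid; linear interpolation).  The exact rate functions above stay
// the single source of truth: tables are rebuilt from them for each run's dt.
// ---------------------------------------------------------------------------

struct GateLUT { std::vector<double> xinf, dec; };

struct ClassLUT {
  double vmin, dv, inv_dv;
  int npts;
  GateLUT n, m, h, mca, hca, p;
  bool is_exc;
};

static void fill_gate(GateLUT& g, int npts, double vmin, double dv, double dt,
                      GateRates (*rates)(double)) {
  g.xinf.resize(npts); g.dec.resize(npts);
  for (int i = 0; i < npts; ++i) {
    GateRates r = rates(vmin + i * dv);
    g.xinf[i] = gate_inf(r);
    g.dec[i] = std::exp(-dt / gate_tau(r));
  }
}

static ClassLUT build_class_lut(bool is_exc, double dt) {
  ClassLUT t;
  t.vmin = -150.0; t.dv = 0.02; t.npts = (int)((100.0 - t.vmin) / t.dv) + 2;
  t.inv_dv = 1.0 / t.dv;
  t.is_exc = is_exc;
  if (is_exc) {
    fill_gate(t.n, t.npts, t.vmin, t.dv, dt, exc_n);
    fill_gate(t.m, t.npts, t.vmin, t.dv, dt, exc_m);
    fill_gate(t.h, t.npts, t.vmin, t.dv, dt, exc_h);
    fill_gate(t.mca, t.npts, t.vmin, t.dv, dt, exc_mca);
    fill_gate(t.hca, t.npts, t.vmin, t.dv, dt, exc_hca);
    t.p.xinf.resize(t.npts); t.p.dec.resize(t.npts);
    for (int i = 0; i < t.npts; ++i) {
      double v = t.vmin + i * t.dv;
      t.p.xinf[i] = exc_pinf(v);
      t.p.dec[i] = std::exp(-dt / exc_taup(v));
    }
  } else {
    fill_gate(t.n, t.npts, t.vmin, t.dv, dt, inh_n);
    fill_gate(t.m, t.npts, t.vmin, t.dv, dt, inh_m);
    fill_gate(t.h, t.npts, t.vmin, t.dv, dt, inh_h);
  }
  return t;
}

static inline double lut_gate(const GateLUT& g, double x, int i0, double fr) {
  double xinf = g.xinf[i0] + fr * (g.xinf[i0 + 1] - g.xinf[i0]);
  double dec  = g.dec[i0]  + fr * (g.dec[i0 + 1]  - g.dec[i0]);
  double xn = xinf + (x - xinf) * dec;
  if (xn < 0.0) xn = 0.0; else if (xn > 1.0) xn = 1.0;
  return xn;
}

// fast normal deviates: xoshiro256++ with Box-Muller, seeded from R's RNG so
// set.seed() fully determines a run.
struct FastNorm {
  uint64_t s[4];
  bool have;
  double cached;
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    have = false; cached = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline double rnorm() {
    if (have) { have = false; return cached; }
    double u1 = runif(), u2 = runif();
    while (u1 <= 1e-300) u1 = runif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cached = r * std::sin(a); have = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// cell classes
// ---------------------------------------------------------------------------

struct CellClass {
  bool  is_exc;
  double area_cm2, c_nf;
  double gl_us, el;
  double gk_us, ek;
  double gna_us, ena;
  double gca_us, eca;
  double gcan_us, ecan;
  double gm_us, em;
  double tau_ca_ms, ca_inf, ku, depth_um;
  double noise_sd_mv;      // per reference step
  double spike_thresh_mv, refrac_ms;
};

static CellClass cell_from_list(const List& p) {
  CellClass c;
  c.is_exc   = as<bool>(p["is_exc"]);
  c.area_cm2 = as<double>(p["area_cm2"]);
  c.c_nf     = as<double>(p["capacitance_uf_cm2"]) * c.area_cm2 * 1e3;
  // specific conductances arrive in mS/cm2; x area x 1e3 -> uS
  c.gl_us  = as<double>(p["g_l"])  * c.area_cm2 * 1e3;  c.el  = as<double>(p["e_l"]);
  c.gk_us  = as<double>(p["g_k"])  * c.area_cm2 * 1e3;  c.ek  = as<double>(p["e_k"]);
  c.gna_us = as<double>(p["g_na"]) * c.area_cm2 * 1e3;  c.ena = as<double>(p["e_na"]);
  c.gca_us = as<double>(p["g_ca"]) * c.area_cm2 * 1e3;  c.eca = as<double>(p["e_ca"]);
  c.gcan_us= as<double>(p["g_can"])* c.area_cm2 * 1e3;  c.ecan= as<double>(p["e_can"]);
  c.gm_us  = as<double>(p["g_m"])  * c.area_cm2 * 1e3;  c.em  = as<double>(p["e_m"]);
  c.tau_ca_ms = as<double>(p["tau_ca_ms"]);
  c.ca_inf    = as<double>(p["ca_inf"]);
  c.ku        = as<double>(p["k_u"]);
  c.depth_um  = as<double>(p["depth_um"]);
  c.noise_sd_mv = as<double>(p["noise_sd_uv"]) * 1e-3;
  c.spike_thresh_mv = as<double>(p["spike_thresh_mv"]);
  c.refrac_ms = as<double>(p["refractory_ms"]);
  return c;
}

static const double FARADAY = 96485.33212; // C/mol

// per-neuron dynamic state
struct NeuronState {
  double v;
  double n, m, h, mca, hca, p, mcan;
  double ca;
  double last_spike;
};

static void init_state(NeuronState& s, const CellClass& c, double v0) {
  s.v = v0;
  s.n = gate_inf(c.is_exc ? exc_n(v0) : inh_n(v0));
  s.m = gate_inf(c.is_exc ? exc_m(v0) : inh_m(v0));
  s.h = gate_inf(c.is_exc ? exc_h(v0) : inh_h(v0));
  if (c.is_exc) {
    s.mca = gate_inf(exc_mca(v0));
    s.hca = gate_inf(exc_hca(v0));
    s.p   = exc_pinf(v0);
    s.ca  = c.ca_inf;
    s.mcan= gate_inf(exc_can(s.ca));
  } else {
    s.mca = s.hca = s.p = s.mcan = 0.0;
    s.ca = 0.0;
  }
  s.last_spike = -1e9;
}

struct StepCurrents { double il, ik, ina, ica, ican, im; };

static inline StepCurrents membrane_currents(const NeuronState& s, const CellClass& c) {
  StepCurrents I;
  I.il  = c.gl_us * (s.v - c.el);
  I.ik  = c.gk_us * s.n * s.n * s.n * s.n * (s.v - c.ek);
  I.ina = c.gna_us * s.m * s.m * s.m * s.h * (s.v - c.ena);
  if (c.is_exc) {
    I.ica  = c.gca_us  * s.mca * s.mca * s.hca * (s.v - c.eca);
    I.ican = c.gcan_us * s.mcan * s.mcan       * (s.v - c.ecan);
    I.im   = c.gm_us   * s.p                   * (s.v - c.em);
  } else {
    I.ica = I.ican = I.im = 0.0;
  }
  return I;
}

// advance one neuron by dt; i_in is the total applied current (nA, depolarizing
// positive); returns true when a spike is detected (upward threshold crossing
// outside the hold-off window).
static inline bool step_neuron_core(NeuronState& s, const CellClass& c, double i_in,
                                    double i_syn, double dt, double noise_step_sd,
                                    double t_now, const ClassLUT* lut,
                                    FastNorm* rng) {
  StepCurrents I = membrane_currents(s, c);
  double i_total = -I.il - I.ik - I.ina - I.ica - I.ican - I.im - i_syn + i_in;
  double v_old = s.v;
  double dv = dt * i_total / c.c_nf;
  if (noise_step_sd > 0.0)
    dv += noise_step_sd * (rng ? rng->rnorm() : norm_rand());
  s.v = v_old + dv;
  if (!std::isfinite(s.v)) return false; // caller checks

  if (lut) {
    double vc = v_old;
    if (vc < lut->vmin) vc = lut->vmin;
    double pos = (vc - lut->vmin) * lut->inv_dv;
    int i0 = (int)pos;
    if (i0 > lut->npts - 2) i0 = lut->npts - 2;
    double fr = pos - i0;
    s.n = lut_gate(lut->n, s.n, i0, fr);
    s.m = lut_gate(lut->m, s.m, i0, fr);
    s.h = lut_gate(lut->h, s.h, i0, fr);
    if (c.is_exc) {
      s.mca = lut_gate(lut->mca, s.mca, i0, fr);
      s.hca = lut_gate(lut->hca, s.hca, i0, fr);
      s.p = lut_gate(lut->p, s.p, i0, fr);
      s.mcan = gate_step(s.mcan, exc_can(s.ca), dt);
      // calcium pool in uM: influx k_u * (I/A)[mA/cm^2] / (2 F d[um]) in
      // mM/ms, converted to uM/ms; inward (negative) current raises [Ca]
      double dens = I.ica * 1e-6 / c.area_cm2;                 // mA/cm^2
      double gamma = -c.ku * dens / (2.0 * FARADAY * c.depth_um) * 1e3;
      s.ca += dt * (gamma + (c.ca_inf - s.ca) / c.tau_ca_ms);
      if (s.ca < 0.0) s.ca = 0.0;
    }
  } else if (c.is_exc) {
    s.n = gate_step(s.n, exc_n(v_old), dt);
    s.m = gate_step(s.m, exc_m(v_old), dt);
    s.h = gate_step(s.h, exc_h(v_old), dt);
    s.mca = gate_step(s.mca, exc_mca(v_old), dt);
    s.hca = gate_step(s.hca, exc_hca(v_old), dt);
    double pinf = exc_pinf(v_old), taup = exc_taup(v_old);
    s.p = pinf + (s.p - pinf) * std::exp(-dt / taup);
    s.mcan = gate_step(s.mcan, exc_can(s.ca), dt);
    // calcium pool (explicit Euler, floored at zero)
    // calcium pool in uM (see the table-lookup branch for the convention)
    double dens = I.ica * 1e-6 / c.area_cm2;                   // mA/cm^2
    double gamma = -c.ku * dens / (2.0 * FARADAY * c.depth_um) * 1e3;
    s.ca += dt * (gamma + (c.ca_inf - s.ca) / c.tau_ca_ms);
    if (s.ca < 0.0) s.ca = 0.0;
  } else {
    s.n = gate_step(s.n, inh_n(v_old), dt);
    s.m = gate_step(s.m, inh_m(v_old), dt);
    s.h = gate_step(s.h, inh_h(v_old), dt);
  }

  bool spk = (v_old < c.spike_thresh_mv) && (s.v >= c.spike_thresh_mv) &&
             (t_now - s.last_spike >= c.refrac_ms);
  if (spk) s.last_spike = t_now;
  return spk;
}

// ---------------------------------------------------------------------------
// exposed single-cell helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gating_rates_cpp(double vm, std::string channel, bool is_exc, double ca) {
  GateRates r;
  if (is_exc) {
    if (channel == "n")      r = exc_n(vm);
    else if (channel == "m") r = exc_m(vm);
    else if (channel == "h") r = exc_h(vm);
    else if (channel == "m_ca") r = exc_mca(vm);
    else if (channel == "h_ca") r = exc_hca(vm);
    else if (channel == "m_can") r = exc_can(ca);
    else if (channel == "p") {
      return List::create(_["x_inf"] = exc_pinf(vm), _["tau_ms"] = exc_taup(vm));
    } else stop("unknown channel '%s' for the excitatory class", channel.c_str());
  } else {
    if (channel == "n")      r = inh_n_raw(vm);
    else if (channel == "m") r = inh_m_raw(vm);
    else if (channel == "h") r = inh_h_raw(vm);
    else stop("unknown channel '%s' for the inhibitory class", channel.c_str());
    return List::create(_["alpha"] = r.a, _["beta"] = r.b,
                        _["x_inf"] = gate_inf(r),
                        _["tau_ms"] = gate_tau(phi_scale(r, PHI_INH)));
  }
  if (channel == "m_can") {
    GateRates rr = exc_can_raw(ca);
    return List::create(_["alpha"] = rr.a, _["beta"] = rr.b,
                        _["x_inf"] = gate_inf(rr),
                        _["tau_ms"] = gate_tau(phi_scale(rr, PHI_CAN)));
  }
  return List::create(_["alpha"] = r.a, _["beta"] = r.b,
                      _["x_inf"] = gate_inf(r), _["tau_ms"] = gate_tau(r));
}

// [[Rcpp::export]]
List sim_neuron_cpp(List cell, double v0, NumericVector i_ext, double dt,
                    double noise_ref_ms, bool noise_on, bool record) {
  CellClass c = cell_from_list(cell);
  NeuronState s;
  init_state(s, c, v0);
  int n = i_ext.size();
  double noise_sd = noise_on ? c.noise_sd_mv * std::sqrt(dt / noise_ref_ms) : 0.0;
  ClassLUT lut = build_class_lut(c.is_exc, dt);
  std::vector<double> spikes;
  NumericVector v_tr, ca_tr, ican_tr, im_tr;
  if (record) { v_tr = NumericVector(n); ca_tr = NumericVector(n);
                ican_tr = NumericVector(n); im_tr = NumericVector(n); }
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    bool spk = step_neuron_core(s, c, i_ext[i], 0.0, dt, noise_sd, t, &lut, 0);
    if (!std::isfinite(s.v))
      stop("membrane integration diverged at t = %.2f ms", t);
    if (spk) spikes.push_back(t);
    if (record) {
      v_tr[i] = s.v; ca_tr[i] = s.ca;
      StepCurrents I = membrane_currents(s, c);
      ican_tr[i] = I.ican; im_tr[i] = I.im;
    }
  }
  List out = List::create(
    _["spike_times_ms"] = wrap(spikes),
    _["state"] = List::create(_["vm_mv"] = s.v, _["n"] = s.n, _["m"] = s.m,
                              _["h"] = s.h, _["m_ca"] = s.mca, _["h_ca"] = s.hca,
                              _["p"] = s.p, _["m_can"] = s.mcan,
                              _["ca_molar"] = s.ca,
                              _["last_spike_ms"] = s.last_spike));
  if (record) {
    out["vm_mv"] = v_tr; out["ca_molar"] = ca_tr;
    out["i_can_na"] = ican_tr; out["i_m_na"] = im_tr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// full network simulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_network_cpp(List net, List kur, List stim, List ext, List run) {
  // --- network description -------------------------------------------------
  IntegerVector class_id = net["class_id"];        // 0 exc, 1 inh
  List exc_par = net["exc_params"], inh_par = net["inh_params"];
  CellClass cls[2] = { cell_from_list(exc_par), cell_from_list(inh_par) };
  int n_neuron = class_id.size();

  IntegerVector edge_ptr  = net["edge_ptr"];       // CSR by presynaptic neuron
  IntegerVector edge_post = net["edge_post"];      // 0-based
  NumericVector edge_w    = net["edge_w_us"];

  NumericVector syn_tau = net["syn_tau_ms"];       // taug_e, tauh_e, taug_i, tauh_i
  double e_rev_e = as<double>(net["e_rev_e"]), e_rev_i = as<double>(net["e_rev_i"]);
  IntegerVector theta_target = net["theta_target"];// neurons receiving I_theta
  IntegerVector ca1e_idx     = net["ca1_exc"];     // neurons driving X(t)
  NumericVector v0 = net["v0"];

  // --- oscillator ensemble -------------------------------------------------
  NumericVector theta0 = kur["phases"];
  NumericVector omega  = kur["omega_rad_s"];
  int n_osc = theta0.size();
  double k_sync   = as<double>(kur["sync_ratio"]);
  double g_reset  = as<double>(kur["reset_gain"]);
  double th_peak  = as<double>(kur["peak_phase_rad"]);
  double ph_off   = as<double>(kur["phase_offset_rad"]);
  double g_theta  = as<double>(kur["theta_gain_na"]);
  double tau_fr_ms= as<double>(kur["rate_time_constant_ms"]);
  bool reset_on   = as<bool>(kur["reset_on"]);
  std::vector<double> th(theta0.begin(), theta0.end());

  // --- stimulation protocol ------------------------------------------------
  // mode: 0 none, 1 explicit onsets, 2 single pulse at phase, 3 train (onset
  // at phase or immediately), applied to stim_target neurons.
  int stim_mode = as<int>(stim["mode"]);
  NumericVector stim_onsets = stim["onsets_ms"];
  double stim_amp   = as<double>(stim["amplitude_na"]);
  double stim_width = as<double>(stim["pulse_width_ms"]);
  double stim_phase = as<double>(stim["target_phase_rad"]);
  double stim_tol   = as<double>(stim["phase_tol_rad"]);
  double stim_arm   = as<double>(stim["arm_time_ms"]);
  double train_hz   = as<double>(stim["train_frequency_hz"]);
  double train_dur  = as<double>(stim["train_duration_ms"]);
  IntegerVector stim_target = stim["target"];

  // --- extra current injections (ramps, tuning sinusoids, pulsed drive) ----
  NumericMatrix ext_cur = ext["current_na"];       // n_steps x n_groups (or 0x0)
  List ext_groups = ext["groups"];

  // --- run parameters ------------------------------------------------------
  double dt = as<double>(run["dt_ms"]);
  int n_steps = as<int>(run["n_steps"]);
  bool noise_on = as<bool>(run["noise_on"]);
  double noise_ref = as<double>(run["noise_ref_ms"]);
  IntegerVector mon_idx = run["monitor_idx"];
  bool keep_theta = as<bool>(run["record_theta"]);

  // synapse propagator constants (exact solution of the linear cascade)
  double eg_e = std::exp(-dt / syn_tau[0]), eh_e = std::exp(-dt / syn_tau[1]);
  double cf_e = (syn_tau[1] / (syn_tau[1] - syn_tau[0])) * (eh_e - eg_e);
  double eg_i = std::exp(-dt / syn_tau[2]), eh_i = std::exp(-dt / syn_tau[3]);
  double cf_i = (syn_tau[3] / (syn_tau[3] - syn_tau[2])) * (eh_i - eg_i);

  std::vector<NeuronState> st(n_neuron);
  std::vector<double> ge(n_neuron, 0.0), he(n_neuron, 0.0);
  std::vector<double> gi(n_neuron, 0.0), hi(n_neuron, 0.0);
  std::vector<char> is_theta_tgt(n_neuron, 0), is_stim_tgt(n_neuron, 0);
  for (int i = 0; i < n_neuron; ++i) init_state(st[i], cls[class_id[i]], v0[i]);
  for (int i = 0; i < theta_target.size(); ++i) is_theta_tgt[theta_target[i]] = 1;
  for (int i = 0; i < stim_target.size(); ++i)  is_stim_tgt[stim_target[i]] = 1;

  int n_groups = ext_cur.ncol();
  std::vector< std::vector<char> > grp(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector gi_ = ext_groups[g];
    grp[g].assign(n_neuron, 0);
    for (int i = 0; i < gi_.size(); ++i) grp[g][gi_[i]] = 1;
  }

  double noise_scale = std::sqrt(dt / noise_ref);
  ClassLUT luts[2] = { build_class_lut(true, dt), build_class_lut(false, dt) };
  FastNorm rng; rng.seed_from_r();
  double n_ca1e = (double) ca1e_idx.size();
  std::vector<char> is_ca1e(n_neuron, 0);
  for (int i = 0; i < ca1e_idx.size(); ++i) is_ca1e[ca1e_idx[i]] = 1;
  double x_decay = std::exp(-dt / tau_fr_ms);
  double x_rate = 0.0;                              // X(t), s^-1

  std::vector<double> spike_t; std::vector<int> spike_id;
  spike_t.reserve(1 << 16); spike_id.reserve(1 << 16);
  NumericVector ser_A, ser_phi, ser_drive, ser_x, ser_stim;
  if (keep_theta) {
    ser_A = NumericVector(n_steps); ser_phi = NumericVector(n_steps);
    ser_drive = NumericVector(n_steps); ser_x = NumericVector(n_steps);
    ser_stim = NumericVector(n_steps);
  }
  int n_mon = mon_idx.size();
  NumericMatrix mon_v, mon_ican, mon_im;
  if (n_mon > 0) {
    mon_v = NumericMatrix(n_steps, n_mon);
    mon_ican = NumericMatrix(n_steps, n_mon);
    mon_im = NumericMatrix(n_steps, n_mon);
  }

  // stimulation bookkeeping
  bool stim_armed = (stim_mode == 2) || (stim_mode == 3 && R_finite(stim_phase));
  bool stim_started = (stim_mode == 3 && !R_finite(stim_phase));
  double train_t0 = stim_started ? stim_arm : -1.0;
  double phase_diff_prev = NA_REAL;
  std::vector<double> fired_onsets;
  if (stim_mode == 1)
    fired_onsets.assign(stim_onsets.begin(), stim_onsets.end());

  std::vector<int> step_spikes; step_spikes.reserve(1024);

  for (int tstep = 0; tstep < n_steps; ++tstep) {
    double t = tstep * dt;

    // 1. collective theta state and drive at time t
    double sr = 0.0, si = 0.0;
    for (int i = 0; i < n_osc; ++i) { sr += std::cos(th[i]); si += std::sin(th[i]); }
    sr /= n_osc; si /= n_osc;
    double amp = std::sqrt(sr * sr + si * si);
    double phi = std::atan2(si, sr);
    double i_theta = g_theta * (amp * std::cos(phi) + 1.0) / 2.0;

    // 2. stimulation current at time t
    if (stim_armed && t >= stim_arm) {
      double d = std::atan2(std::sin(phi - stim_phase), std::cos(phi - stim_phase));
      bool hit = false;
      if (!ISNA(phase_diff_prev)) {
        if (phase_diff_prev < 0.0 && d >= 0.0 && (d - phase_diff_prev) < M_PI) hit = true;
      } else if (std::fabs(d) < stim_tol) hit = true;
      phase_diff_prev = d;
      if (hit) {
        stim_armed = false;
        if (stim_mode == 2) fired_onsets.push_back(t);
        else { stim_started = true; train_t0 = t; }
      }
    }
    if (stim_started && train_hz > 0.0) {
      double period = 1000.0 / train_hz;
      double since = t - train_t0;
      if (since >= -1e-9 && since < train_dur) {
        double k = std::floor(since / period + 1e-9);
        double ton = train_t0 + k * period;
        if (t >= ton && t < ton + stim_width &&
            (fired_onsets.empty() || fired_onsets.back() < ton - 1e-9))
          fired_onsets.push_back(ton);
      }
    }
    double i_stim = 0.0;
    if (!fired_onsets.empty()) {
      for (int k = (int)fired_onsets.size() - 1; k >= 0 &&
           fired_onsets[k] > t - stim_width - dt; --k) {
        if (t >= fired_onsets[k] - 1e-9 && t < fired_onsets[k] + stim_width - 1e-9) {
          i_stim = stim_amp; break;
        }
      }
    }

    // 3. membrane update
    step_spikes.clear();
    for (int i = 0; i < n_neuron; ++i) {
      const CellClass& c = cls[class_id[i]];
      double i_syn = ge[i] * (st[i].v - e_rev_e) + gi[i] * (st[i].v - e_rev_i);
      double i_in = 0.0;
      if (is_theta_tgt[i]) i_in += i_theta;
      if (is_stim_tgt[i])  i_in += i_stim;
      for (int g = 0; g < n_groups; ++g)
        if (grp[g][i]) i_in += ext_cur(tstep, g);
      double nsd = noise_on ? c.noise_sd_mv * noise_scale : 0.0;
      bool spk = step_neuron_core(st[i], c, i_in, i_syn, dt, nsd, t,
                                  &luts[class_id[i]], &rng);
      if (!std::isfinite(st[i].v))
        stop("integration failure: neuron %d (population class %d) at t = %.2f ms",
             i + 1, class_id[i], t);
      if (spk) { step_spikes.push_back(i); spike_t.push_back(t); spike_id.push_back(i); }
    }

    // 4. synaptic cascade: exact exponential decay, then spike increments
    for (int i = 0; i < n_neuron; ++i) {
      ge[i] = ge[i] * eg_e + he[i] * cf_e;  he[i] *= eh_e;
      gi[i] = gi[i] * eg_i + hi[i] * cf_i;  hi[i] *= eh_i;
    }
    for (size_t sidx = 0; sidx < step_spikes.size(); ++sidx) {
      int pre = step_spikes[sidx];
      bool pre_inh = (class_id[pre] == 1);
      for (int e = edge_ptr[pre]; e < edge_ptr[pre + 1]; ++e) {
        if (pre_inh) hi[edge_post[e]] += edge_w[e];
        else         he[edge_post[e]] += edge_w[e];
      }
    }

    // 5. oscillator phases advance with X from the previous step (one-step lag)
    double dts = dt * 1e-3;                         // ms -> s
    double reset_in = reset_on ? g_reset * x_rate : 0.0;
    for (int i = 0; i < n_osc; ++i) {
      double coupling = k_sync * amp * std::sin(phi - th[i]);
      double z = -std::sin(th[i] - (th_peak + ph_off));
      th[i] += dts * (omega[i] + coupling + reset_in * z);
      if (th[i] > M_PI)  th[i] -= 2.0 * M_PI * std::floor((th[i] + M_PI) / (2.0 * M_PI));
      if (th[i] < -M_PI) th[i] += 2.0 * M_PI * std::floor((M_PI - th[i]) / (2.0 * M_PI));
    }

    // 6. CA1 excitatory population rate X(t)
    x_rate *= x_decay;
    if (n_ca1e > 0) {
      int nsp = 0;
      for (size_t sidx = 0; sidx < step_spikes.size(); ++sidx)
        if (is_ca1e[step_spikes[sidx]]) ++nsp;
      x_rate += nsp / (n_ca1e * tau_fr_ms * 1e-3);
    }

    if (keep_theta) {
      ser_A[tstep] = amp; ser_phi[tstep] = phi; ser_drive[tstep] = i_theta;
      ser_x[tstep] = x_rate; ser_stim[tstep] = i_stim;
    }
    if (n_mon > 0) {
      for (int j = 0; j < n_mon; ++j) {
        const NeuronState& s = st[mon_idx[j]];
        mon_v(tstep, j) = s.v;
        StepCurrents I = membrane_currents(s, cls[class_id[mon_idx[j]]]);
        mon_ican(tstep, j) = I.ican; mon_im(tstep, j) = I.im;
      }
    }
    if (tstep % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["spike_t_ms"] = wrap(spike_t),
    _["spike_id"]   = wrap(spike_id),
    _["stim_onsets_ms"] = wrap(fired_onsets),
    _["phases"] = wrap(th),
    _["stim_triggered"] = !stim_armed);
  if (keep_theta) {
    out["theta_amplitude"] = ser_A; out["theta_phase"] = ser_phi;
    out["theta_drive_na"] = ser_drive; out["ca1_rate"] = ser_x;
    out["stim_na"] = ser_stim;
  }
  if (n_mon > 0) {
    out["monitor_v"] = mon_v; out["monitor_i_can"] = mon_ican;
    out["monitor_i_m"] = mon_im;
  }
  return out;
}

// ---------------------------------------------------------------------------
// spatial placement and wiring
// ---------------------------------------------------------------------------

static inline bool in_polygon(double x, double y,
                              const NumericVector& px, const NumericVector& py) {
  int n = px.size(); bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector x, NumericVector y,
                                    NumericVector px, NumericVector py) {
  int n = x.size(); LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = in_polygon(x[i], y[i], px, py);
  return out;
}

// Blue-noise (Poisson-disk) dart throwing inside a polygon with a background
// acceleration grid.  Returns up to n points with pairwise distance >= r.
// [[Rcpp::export]]
NumericMatrix poisson_disk_cpp(int n, double r, NumericVector px, NumericVector py,
                               int max_attempts) {
  double xmin = min(px), xmax = max(px), ymin = min(py), ymax = max(py);
  double cell = r / std::sqrt(2.0);
  int nx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
  int ny = std::max(1, (int)std::ceil((ymax - ymin) / cell));
  std::vector<int> grid((size_t)nx * ny, -1);
  std::vector<double> ptx, pty;
  ptx.reserve(n); pty.reserve(n);
  double r2 = r * r;
  int attempts = 0;
  while ((int)ptx.size() < n && attempts < max_attempts) {
    ++attempts;
    double x = xmin + unif_rand() * (xmax - xmin);
    double y = ymin + unif_rand() * (ymax - ymin);
    if (!in_polygon(x, y, px, py)) continue;
    int gx = (int)((x - xmin) / cell), gy = (int)((y - ymin) / cell);
    bool ok = true;
    for (int ix = std::max(0, gx - 2); ix <= std::min(nx - 1, gx + 2) && ok; ++ix)
      for (int iy = std::max(0, gy - 2); iy <= std::min(ny - 1, gy + 2) && ok; ++iy) {
        int id = grid[(size_t)ix * ny + iy];
        if (id >= 0) {
          double dx = ptx[id] - x, dy = pty[id] - y;
          if (dx * dx + dy * dy < r2) ok = false;
        }
      }
    if (!ok) continue;
    grid[(size_t)gx * ny + gy] = (int)ptx.size();
    ptx.push_back(x); pty.push_back(y);
  }
  NumericMatrix out(ptx.size(), 2);
  for (size_t i = 0; i < ptx.size(); ++i) { out(i, 0) = ptx[i]; out(i, 1) = pty[i]; }
  return out;
}

// Discrete Lloyd relaxation (centroidal Voronoi) of sites against a fixed set
// of uniform samples of the domain.  Energy = mean squared sample-to-nearest-
// site distance; iteration stops at max_iter or a relative energy change
// below tol.
// [[Rcpp::export]]
List lloyd_relax_cpp(NumericMatrix sites, NumericMatrix samples,
                     int max_iter, double tol) {
  int ns = sites.nrow(), np = samples.nrow();
  std::vector<double> sx(ns), sy(ns);
  for (int i = 0; i < ns; ++i) { sx[i] = sites(i, 0); sy[i] = sites(i, 1); }
  std::vector<double> energy;
  std::vector<double> cx(ns), cy(ns); std::vector<int> cnt(ns);

  double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
  for (int p = 0; p < np; ++p) {
    xmin = std::min(xmin, samples(p,0)); xmax = std::max(xmax, samples(p,0));
    ymin = std::min(ymin, samples(p,1)); ymax = std::max(ymax, samples(p,1));
  }
  double span = std::max(xmax - xmin, ymax - ymin) + 1e-9;
  int ng = std::max(1, (int)std::floor(std::sqrt((double)ns)));
  double cell = span / ng;
  int nx = (int)std::ceil((xmax - xmin) / cell) + 1;
  int ny = (int)std::ceil((ymax - ymin) / cell) + 1;

  for (int it = 0; it < max_iter; ++it) {
    // rebuild site grid
    std::vector< std::vector<int> > grid((size_t)nx * ny);
    for (int i = 0; i < ns; ++i) {
      int gx = std::min(nx - 1, std::max(0, (int)((sx[i] - xmin) / cell)));
      int gy = std::min(ny - 1, std::max(0, (int)((sy[i] - ymin) / cell)));
      grid[(size_t)gx * ny + gy].push_back(i);
    }
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    double e = 0.0;
    for (int p = 0; p < np; ++p) {
      double x = samples(p, 0), y = samples(p, 1);
      int gx = std::min(nx - 1, std::max(0, (int)((x - xmin) / cell)));
      int gy = std::min(ny - 1, std::max(0, (int)((y - ymin) / cell)));
      int best = -1; double bd = 1e300;
      for (int ring = 0; ring < std::max(nx, ny); ++ring) {
        int x0 = std::max(0, gx - ring), x1 = std::min(nx - 1, gx + ring);
        int y0 = std::max(0, gy - ring), y1 = std::min(ny - 1, gy + ring);
        for (int ix = x0; ix <= x1; ++ix)
          for (int iy = y0; iy <= y1; ++iy) {
            if (ring > 0 && ix > x0 && ix < x1 && iy > y0 && iy < y1) continue;
            const std::vector<int>& cellv = grid[(size_t)ix * ny + iy];
            for (size_t q = 0; q < cellv.size(); ++q) {
              double dx = sx[cellv[q]] - x, dy = sy[cellv[q]] - y;
              double d = dx * dx + dy * dy;
              if (d < bd) { bd = d; best = cellv[q]; }
            }
          }
        if (best >= 0 && std::sqrt(bd) <= (double)ring * cell) break;
      }
      cx[best] += x; cy[best] += y; ++cnt[best]; e += bd;
    }
    e /= np;
    energy.push_back(e);
    for (int i = 0; i < ns; ++i)
      if (cnt[i] > 0) { sx[i] = cx[i] / cnt[i]; sy[i] = cy[i] / cnt[i]; }
    if (it > 0) {
      double rel = std::fabs(energy[it - 1] - e) / std::max(e, 1e-300);
      if (rel < tol) break;
    }
    if (it % 10 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(ns, 2);
  for (int i = 0; i < ns; ++i) { out(i, 0) = sx[i]; out(i, 1) = sy[i]; }
  return List::create(_["sites"] = out, _["energy"] = wrap(energy));
}

// Distance-decayed Bernoulli wiring within one region (full 3D distance).
// [[Rcpp::export]]
List connect_pairs_cpp(NumericMatrix pre_xyz, NumericMatrix post_xyz,
                       double a_max, double sigma_um, bool same_population,
                       bool z_only, bool clip_one) {
  int npre = pre_xyz.nrow(), npost = post_xyz.nrow();
  std::vector<int> from, to;
  double s2 = 2.0 * sigma_um * sigma_um;
  for (int i = 0; i < npre; ++i) {
    double xi = pre_xyz(i, 0), yi = pre_xyz(i, 1), zi = pre_xyz(i, 2);
    for (int j = 0; j < npost; ++j) {
      if (same_population && i == j) continue;
      double p;
      if (z_only) {
        double dz = zi - post_xyz(j, 2);
        p = a_max * std::exp(-dz * dz / s2);
        if (clip_one && p > 1.0) p = 1.0;
      } else {
        double dx = xi - post_xyz(j, 0), dy = yi - post_xyz(j, 1), dz = zi - post_xyz(j, 2);
        p = a_max * std::exp(-(dx * dx + dy * dy + dz * dz) / s2);
      }
      if (p > 0.0 && unif_rand() < p) { from.push_back(i + 1); to.push_back(j + 1); }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pre"] = wrap(from), _["post"] = wrap(to));
}
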
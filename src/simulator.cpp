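// Core integrator for the three-cell pyloric network model.
//
// Single-compartment cells with eight currents (Na, CaT, CaS, A, KCa, Kd, H,
// leak), first-order gating kinetics from the Prinz/Bucher/Marder STG cell
// model, calcium buffering with time constant tauCa, and seven graded
// inhibitory synapses of two transmitter classes.  Temperature enters through
// Q10 Arrhenius factors on conductances (multiplied) and time constants
// (divided) and through the Nernst calcium reversal potential.
//
// Units: mV, nA, uS, ms, uM throughout.  State layout (46 components):
//   per cell (PD, LP, PY): V, mNa, hNa, mCaT, hCaT, mCaS, hCaS, mA, hA,
//                          mKCa, mKd, mH, Ca            (13 each)
//   then 7 synaptic activations s.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// fixed biophysical constants
// ---------------------------------------------------------------------------
static const double CAP_NF      = 0.628;   // membrane capacitance, nF
static const double E_NA        = 50.0;    // mV
static const double E_K         = -80.0;   // mV
static const double E_H         = -20.0;   // mV
static const double E_LEAK      = -50.0;   // mV
static const double CA_OUT      = 3000.0;  // uM extracellular calcium
static const double CA_REST     = 0.05;    // uM resting intracellular calcium
static const double CA_INFLUX_F = 14.96;   // uM/nA calcium influx factor
static const double V_TH_SYN    = -35.0;   // mV synaptic half-activation
static const double DELTA_SYN   = 5.0;     // mV synaptic activation slope
static const double TAU_R_SYN   = 20.0;    // ms synaptic timescale floor
// transmitter classes: 0 = glutamatergic, 1 = cholinergic
static const double K_MINUS[2]  = {1.0 / 40.0, 1.0 / 100.0};  // 1/ms
static const double E_SYN[2]    = {-70.0, -80.0};             // mV
// wiring: 7 synapses (pre, post, class); cells PD=0, LP=1, PY=2
static const int SYN_PRE[7]   = {0, 0, 0, 0, 1, 1, 2};
static const int SYN_POST[7]  = {1, 1, 2, 2, 0, 2, 1};
static const int SYN_CLASS[7] = {0, 1, 0, 1, 0, 0, 0};
// gas constant / Faraday, for the divalent Nernst potential in mV
static const double R_GAS = 8.314462618;   // J/(mol K)
static const double FARADAY = 96485.33212; // C/mol

// channels: 0 Na, 1 CaT, 2 CaS, 3 A, 4 KCa, 5 Kd, 6 H, 7 leak
// gates:    0 Na-m, 1 Na-h, 2 CaT-m, 3 CaT-h, 4 CaS-m, 5 CaS-h,
//           6 A-m, 7 A-h, 8 KCa-m, 9 Kd-m, 10 H-m
static const int GATE_CHANNEL[11] = {0, 0, 1, 1, 2, 2, 3, 3, 4, 5, 6};

static inline double sigm(double v, double vhalf, double k) {
  // logistic steady state: 1/(1+exp((v+vhalf)/k)); k < 0 for activation
  return 1.0 / (1.0 + std::exp((v + vhalf) / k));
}

// steady-state of gate g at voltage v; KCa (gate 8) returns the
// voltage-dependent part only, the caller multiplies Ca/(Ca+3)
static double gate_inf(int g, double v) {
  switch (g) {
  case 0:  return sigm(v, 25.5, -5.29);   // Na m
  case 1:  return sigm(v, 48.9, 5.18);    // Na h
  case 2:  return sigm(v, 27.1, -7.2);    // CaT m
  case 3:  return sigm(v, 32.1, 5.5);     // CaT h
  case 4:  return sigm(v, 33.0, -8.1);    // CaS m
  case 5:  return sigm(v, 60.0, 6.2);     // CaS h
  case 6:  return sigm(v, 27.2, -8.7);    // A m
  case 7:  return sigm(v, 56.9, 4.9);     // A h
  case 8:  return sigm(v, 28.3, -12.6);   // KCa m (voltage part)
  case 9:  return sigm(v, 12.3, -11.8);   // Kd m
  case 10: return sigm(v, 75.0, 5.5);     // H m
  }
  return NA_REAL;
}

static double gate_tau(int g, double v) {
  switch (g) {
  case 0:  return 2.64 - 2.52 * sigm(v, 120.0, -25.0);            // Na m
  case 1:  return (1.34 * sigm(v, 62.9, -10.0)) *
                  (1.5 + sigm(v, 34.9, 3.6));                     // Na h
  case 2:  return 43.4 - 42.6 * sigm(v, 68.1, -20.5);             // CaT m
  case 3:  return 210.0 - 179.6 * sigm(v, 55.0, -16.9);           // CaT h
  case 4:  return 2.8 + 14.0 /
                  (std::exp((v + 27.0) / 10.0) +
                   std::exp((v + 70.0) / -13.0));                 // CaS m
  case 5:  return 120.0 + 300.0 /
                  (std::exp((v + 55.0) / 9.0) +
                   std::exp((v + 65.0) / -16.0));                 // CaS h
  case 6:  return 23.2 - 20.8 * sigm(v, 32.9, -15.2);             // A m
  case 7:  return 77.2 - 58.4 * sigm(v, 38.9, -26.5);             // A h
  case 8:  return 180.6 - 150.2 * sigm(v, 46.0, -22.7);           // KCa m
  case 9:  return 14.4 - 12.8 * sigm(v, 28.3, -19.2);             // Kd m
  case 10: return 2.0 / (std::exp((v + 169.7) / -11.6) +
                         std::exp((v - 26.7) / 14.3));            // H m
  }
  return NA_REAL;
}

// gating exponents m^p and presence of an inactivation gate per channel
static const int GATE_P[8] = {3, 3, 3, 3, 4, 4, 1, 0};

// ---------------------------------------------------------------------------
// tabulated kinetics (optional fast path)
// ---------------------------------------------------------------------------
// Linear-interpolation tables on a 0.02 mV grid over [-150, 100] mV for the
// 11 gate steady states, 11 gate time constants, and the synaptic sigmoid.
// Interpolation error is < 1e-6 relative; endpoints clamp (all functions
// saturate).  Used by the optimizer where throughput dominates.
static const double TAB_VMIN = -150.0, TAB_VMAX = 100.0, TAB_DV = 0.02;
static const int TAB_N = 12501;
static std::vector<double> tab_inf, tab_tau, tab_syn;

static void build_tables() {
  if (!tab_inf.empty()) return;
  tab_inf.resize(11 * TAB_N);
  tab_tau.resize(11 * TAB_N);
  tab_syn.resize(TAB_N);
  for (int i = 0; i < TAB_N; ++i) {
    double v = TAB_VMIN + TAB_DV * i;
    for (int g = 0; g < 11; ++g) {
      tab_inf[g * TAB_N + i] = gate_inf(g, v);
      tab_tau[g * TAB_N + i] = gate_tau(g, v);
    }
    tab_syn[i] = 1.0 / (1.0 + std::exp((V_TH_SYN - v) / DELTA_SYN));
  }
}

static inline double tab_lookup(const std::vector<double>& tab, int g, double v) {
  double x = (v - TAB_VMIN) / TAB_DV;
  if (x <= 0.0) return tab[g * TAB_N];
  if (x >= TAB_N - 1) return tab[g * TAB_N + TAB_N - 1];
  int i = (int)x;
  double f = x - i;
  const double* p = &tab[g * TAB_N + i];
  return p[0] + f * (p[1] - p[0]);
}

// ---------------------------------------------------------------------------
// temperature-scaled parameters
// ---------------------------------------------------------------------------
// q10 layout (24): [0..7] conductance Q10 per channel (Na..leak),
// [8..18] gating-tau Q10 per gate, [19] tauCa Q10,
// [20,21] synaptic conductance Q10 (glut, chol), [22,23] synaptic tau Q10.
struct ScaledParams {
  double g[3][8];      // temperature-scaled maximal conductances
  double tauCa[3];     // ms (unscaled; rate factor applied separately)
  double gsyn[7];      // temperature-scaled synaptic conductances
  double rtau[11];     // rate factor multiplying 1/tau per gate
  double rtauCa;       // rate factor for calcium buffering
  double rsyn[2];      // rate factor for synaptic activation per class
  double nernst_fac;   // R T / (2 F) in mV at the ECa temperature
};

static inline double q10_factor(double q10, double T, double Tref) {
  return std::pow(q10, (T - Tref) / 10.0);
}

// gbase: 27 intrinsic (9 per cell: gNa..gleak, tauCa), gsyn: 7,
// gscale: 34 multipliers (24 intrinsic conductances by cell-major
// [cell*8+chan], then 7 synaptic, then 3 tauCa multipliers)
static void scale_params(const double* gbase, const double* gsyn,
                         const double* q10, double T, double Tref,
                         double Teca, const double* gscale,
                         ScaledParams& sp) {
  double rg[8], rt[11];
  for (int c = 0; c < 8; ++c) rg[c] = q10_factor(q10[c], T, Tref);
  for (int g = 0; g < 11; ++g) rt[g] = q10_factor(q10[8 + g], T, Tref);
  for (int cell = 0; cell < 3; ++cell) {
    for (int c = 0; c < 8; ++c) {
      double s = gscale ? gscale[cell * 8 + c] : 1.0;
      sp.g[cell][c] = gbase[cell * 9 + c] * rg[c] * s;
    }
    double st = gscale ? gscale[31 + cell] : 1.0;
    sp.tauCa[cell] = gbase[cell * 9 + 8] * st;
  }
  double rsg[2] = {q10_factor(q10[20], T, Tref), q10_factor(q10[21], T, Tref)};
  for (int s = 0; s < 7; ++s) {
    double sc = gscale ? gscale[24 + s] : 1.0;
    sp.gsyn[s] = gsyn[s] * rsg[SYN_CLASS[s]] * sc;
  }
  for (int g = 0; g < 11; ++g) sp.rtau[g] = rt[g];
  sp.rtauCa = q10_factor(q10[19], T, Tref);
  sp.rsyn[0] = q10_factor(q10[22], T, Tref);
  sp.rsyn[1] = q10_factor(q10[23], T, Tref);
  sp.nernst_fac = 1000.0 * R_GAS * (273.15 + Teca) / (2.0 * FARADAY);
}

// ---------------------------------------------------------------------------
// derivative of the full 46-dimensional state
// ---------------------------------------------------------------------------
// If `cur` is non-null it receives the 24 intrinsic currents (cell-major,
// outward positive) followed by the 7 synaptic currents.
static void net_deriv(const double* y, const ScaledParams& sp, bool fast,
                      double* dy, double* cur) {
  double syn_in[3] = {0.0, 0.0, 0.0};  // summed synaptic current per cell
  // synapses first (they only need presynaptic V and s)
  for (int s = 0; s < 7; ++s) {
    double vpre = y[13 * SYN_PRE[s]];
    double vpost = y[13 * SYN_POST[s]];
    double sact = y[39 + s];
    double sinf;
    if (fast) sinf = tab_lookup(tab_syn, 0, vpre);
    else      sinf = 1.0 / (1.0 + std::exp((V_TH_SYN - vpre) / DELTA_SYN));
    double taus = (1.0 - sinf) / K_MINUS[SYN_CLASS[s]];
    dy[39 + s] = (sinf - sact) * sp.rsyn[SYN_CLASS[s]] / (TAU_R_SYN + taus);
    double isyn = sp.gsyn[s] * sact * (vpost - E_SYN[SYN_CLASS[s]]);
    syn_in[SYN_POST[s]] += isyn;
    if (cur) cur[24 + s] = isyn;
  }
  for (int cell = 0; cell < 3; ++cell) {
    const double* yc = y + 13 * cell;
    double* dyc = dy + 13 * cell;
    double v = yc[0], ca = yc[12];
    if (ca < 1e-12) ca = 1e-12;
    double eca = sp.nernst_fac * std::log(CA_OUT / ca);
    double erev[8] = {E_NA, eca, eca, E_K, E_K, E_K, E_H, E_LEAK};
    double itot = 0.0, ica = 0.0;
    for (int g = 0; g < 11; ++g) {
      double xinf, taux;
      if (fast) {
        xinf = tab_lookup(tab_inf, g, v);
        taux = tab_lookup(tab_tau, g, v);
      } else {
        xinf = gate_inf(g, v);
        taux = gate_tau(g, v);
      }
      if (g == 8) xinf *= ca / (ca + 3.0);
      dyc[1 + g] = (xinf - yc[1 + g]) * sp.rtau[g] / taux;
    }
    // per-channel currents: m^p * h * g * (V - E)
    double gate_m[8] = {yc[1], yc[3], yc[5], yc[7], yc[9], yc[10], yc[11], 1.0};
    double gate_h[8] = {yc[2], yc[4], yc[6], yc[8], 1.0, 1.0, 1.0, 1.0};
    for (int c = 0; c < 8; ++c) {
      double m = gate_m[c], act = 1.0;
      switch (GATE_P[c]) {
      case 4: act = m * m * m * m; break;
      case 3: act = m * m * m; break;
      case 1: act = m; break;
      case 0: act = 1.0; break;
      }
      double ic = sp.g[cell][c] * act * gate_h[c] * (v - erev[c]);
      itot += ic;
      if (c == 1 || c == 2) ica += ic;
      if (cur) cur[cell * 8 + c] = ic;
    }
    dyc[0] = -(itot + syn_in[cell]) / CAP_NF;
    dyc[12] = (-CA_INFLUX_F * ica - ca + CA_REST) * sp.rtauCa / sp.tauCa[cell];
  }
}

// temperature at time t (ms) from a schedule matrix (time ms, T degC),
// piecewise-linear, constant extrapolation beyond the ends
static double sched_temp(const NumericMatrix& sched, double t) {
  int n = sched.nrow();
  if (n == 1 || t <= sched(0, 0)) return sched(0, 1);
  if (t >= sched(n - 1, 0)) return sched(n - 1, 1);
  int i = 1;
  while (sched(i, 0) < t) ++i;
  double t0 = sched(i - 1, 0), t1 = sched(i, 0);
  double f = (t - t0) / (t1 - t0);
  return sched(i - 1, 1) + f * (sched(i, 1) - sched(i - 1, 1));
}

static inline void clamp_state(double* y) {
  for (int cell = 0; cell < 3; ++cell) {
    double* yc = y + 13 * cell;
    for (int g = 1; g <= 11; ++g) {
      if (yc[g] < 0.0) yc[g] = 0.0;
      else if (yc[g] > 1.0) yc[g] = 1.0;
    }
    if (yc[12] < 1e-9) yc[12] = 1e-9;
  }
  for (int s = 39; s < 46; ++s) {
    if (y[s] < 0.0) y[s] = 0.0;
    else if (y[s] > 1.0) y[s] = 1.0;
  }
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".gate_inf_tau_cpp")]]
NumericVector gate_inf_tau_cpp(int gate, double v, double ca) {
  if (gate < 0 || gate > 10) stop("unknown gate index");
  double xinf = gate_inf(gate, v);
  if (gate == 8) xinf *= ca / (ca + 3.0);
  return NumericVector::create(_["inf"] = xinf, _["tau"] = gate_tau(gate, v));
}

// [[Rcpp::export(name = ".nernst_eca_cpp")]]
double nernst_eca_cpp(double ca_in, double temp_c, double ca_out) {
  if (ca_in <= 0) stop("intracellular calcium must be positive");
  return 1000.0 * R_GAS * (273.15 + temp_c) / (2.0 * FARADAY) *
         std::log(ca_out / ca_in);
}

// [[Rcpp::export(name = ".net_deriv_cpp")]]
NumericVector net_deriv_cpp(NumericVector state, NumericVector gbase,
                            NumericVector gsyn, NumericVector q10,
                            double temp, double tref, double teca,
                            Nullable<NumericVector> gscale) {
  if (state.size() != 46) stop("state must have 46 components");
  for (int i = 0; i < 46; ++i)
    if (!std::isfinite(state[i])) stop("non-finite state component");
  ScaledParams sp;
  const double* gs = NULL;
  NumericVector gsv;
  if (gscale.isNotNull()) { gsv = gscale.get(); gs = gsv.begin(); }
  scale_params(gbase.begin(), gsyn.begin(), q10.begin(), temp, tref, teca,
               gs, sp);
  NumericVector dy(46);
  net_deriv(state.begin(), sp, false, dy.begin(), NULL);
  return dy;
}

// [[Rcpp::export(name = ".rk4_step_cpp")]]
NumericVector rk4_step_cpp(NumericVector state, NumericVector gbase,
                           NumericVector gsyn, NumericVector q10,
                           double temp, double tref, double teca, double dt) {
  ScaledParams sp;
  scale_params(gbase.begin(), gsyn.begin(), q10.begin(), temp, tref, teca,
               NULL, sp);
  double y[46], k1[46], k2[46], k3[46], k4[46], tmp[46];
  std::copy(state.begin(), state.end(), y);
  net_deriv(y, sp, false, k1, NULL);
  for (int i = 0; i < 46; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  net_deriv(tmp, sp, false, k2, NULL);
  for (int i = 0; i < 46; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  net_deriv(tmp, sp, false, k3, NULL);
  for (int i = 0; i < 46; ++i) tmp[i] = y[i] + dt * k3[i];
  net_deriv(tmp, sp, false, k4, NULL);
  for (int i = 0; i < 46; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  clamp_state(y);
  return NumericVector(y, y + 46);
}

// Main simulation loop.
// record mode: 0 = V only, 1 = V + currents + s + Ca + dV/dt.
// Returns a list with the recorded matrix, the final state, and blow-up info.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector state0, NumericVector gbase, NumericVector gsyn,
                  NumericVector q10, NumericMatrix temp_schedule, double tref,
                  bool pin_eca, double dt, double t_total, double t_discard,
                  int stride, int record_mode, bool fast,
                  Nullable<NumericVector> gscale, double t_switch) {
  if (state0.size() != 46) stop("state must have 46 components");
  if (dt <= 0) stop("dt must be positive");
  if (fast) build_tables();

  long n_steps = (long)std::ceil(t_total / dt - 1e-9);
  long discard_steps = (long)std::ceil(t_discard / dt - 1e-9);
  long n_rec = 0;
  if (discard_steps <= n_steps)
    n_rec = (n_steps - discard_steps) / stride + 1;

  int ncol = record_mode == 1 ? 49 : 5;
  NumericMatrix out((int)n_rec, ncol);

  const double* gs = NULL;
  NumericVector gsv;
  if (gscale.isNotNull()) { gsv = gscale.get(); gs = gsv.begin(); }
  bool const_temp = temp_schedule.nrow() == 1;

  double y[46], k1[46], k2[46], k3[46], k4[46], tmp[46], cur[31];
  std::copy(state0.begin(), state0.end(), y);

  ScaledParams sp;
  double T = sched_temp(temp_schedule, 0.0);
  double teca = pin_eca ? tref : T;
  bool switched = gs != NULL && t_switch <= 0.0;
  scale_params(gbase.begin(), gsyn.begin(), q10.begin(), T, tref, teca,
               switched ? gs : NULL, sp);

  long rec_i = 0;
  double blow_time = -1.0;

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    // refresh scaled parameters when temperature or the switch changes
    if (!const_temp) {
      T = sched_temp(temp_schedule, t);
      teca = pin_eca ? tref : T;
    }
    bool now_switched = gs != NULL && t >= t_switch;
    if (!const_temp || now_switched != switched) {
      switched = now_switched;
      scale_params(gbase.begin(), gsyn.begin(), q10.begin(), T, tref, teca,
                   switched ? gs : NULL, sp);
    }
    // record
    if (step >= discard_steps && (step - discard_steps) % stride == 0 &&
        rec_i < n_rec) {
      out(rec_i, 0) = t;
      out(rec_i, 1) = T;
      out(rec_i, 2) = y[0];
      out(rec_i, 3) = y[13];
      out(rec_i, 4) = y[26];
      if (record_mode == 1) {
        double dy[46];
        net_deriv(y, sp, fast, dy, cur);
        for (int c = 0; c < 31; ++c) out(rec_i, 5 + c) = cur[c];
        for (int s = 0; s < 7; ++s) out(rec_i, 36 + s) = y[39 + s];
        out(rec_i, 43) = y[12];
        out(rec_i, 44) = y[25];
        out(rec_i, 45) = y[38];
        out(rec_i, 46) = dy[0];
        out(rec_i, 47) = dy[13];
        out(rec_i, 48) = dy[26];
      }
      ++rec_i;
    }
    if (step == n_steps) break;
    // RK4 step
    net_deriv(y, sp, fast, k1, NULL);
    for (int i = 0; i < 46; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    net_deriv(tmp, sp, fast, k2, NULL);
    for (int i = 0; i < 46; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    net_deriv(tmp, sp, fast, k3, NULL);
    for (int i = 0; i < 46; ++i) tmp[i] = y[i] + dt * k3[i];
    net_deriv(tmp, sp, fast, k4, NULL);
    for (int i = 0; i < 46; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    clamp_state(y);
    if (!std::isfinite(y[0]) || !std::isfinite(y[13]) || !std::isfinite(y[26]) ||
        std::fabs(y[0]) > 1000.0 || std::fabs(y[13]) > 1000.0 ||
        std::fabs(y[26]) > 1000.0) {
      blow_time = t + dt;
      break;
    }
  }
  if (blow_time >= 0 && rec_i < n_rec) {
    // truncate recording at the blow-up
    out = out(Range(0, rec_i > 0 ? (int)rec_i - 1 : 0), Range(0, ncol - 1));
  }
  return List::create(_["record"] = out,
                      _["final_state"] = NumericVector(y, y + 46),
                      _["blow_time"] = blow_time,
                      _["n_recorded"] = (double)rec_i);
}
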
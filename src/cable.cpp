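// Branched-cable integrator: backward-Euler voltage step with a
// tree-ordered (Hines) direct solve, exact exponential gate updates, and a
// single-pool intracellular Ca2+ with Nernst-computed Ca reversal.
//
// Units: mV, ms, nA, uS, nF; areas cm2; conductance densities S/cm2
// (so density * area * 1e6 = uS, and density * (V - E) = mA/cm2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_CHANNELS = 12;
// channel order (fixed contract with the R side):
// 0 naf, 1 nap, 2 kdr, 3 ka, 4 kd, 5 fahp, 6 sahp, 7 h, 8 cat, 9 can,
// 10 car, 11 cal
static const int N_GATES = 17;
// gate layout: 0 naf.m, 1 naf.h, 2 nap.m, 3 kdr.n, 4 ka.a, 5 ka.b,
// 6 kd.a, 7 kd.b, 8 fahp.w, 9 sahp.q, 10 h.q, 11 cat.m, 12 cat.h,
// 13 can.m, 14 can.h, 15 car.m, 16 car.h  (cal.m treated as instantaneous
// is not: it is gate index shared? cal uses its own gate -> add one more)
// NOTE: cal.m stored as gate 16? -- see table below; actual layout defined
// in gate_spec[].

struct GateDef {
  double vhalf, k;      // x_inf = 1/(1+exp(-(V - vhalf)/k)); k<0 inactivation
  double tau0, tauamp, tauv, taus;  // tau = tau0 + tauamp / cosh((V-tauv)/taus)
};

// voltage-dependent gates (Ca-dependent handled separately)
static const int N_VGATES = 18;
static const GateDef GATES[N_VGATES] = {
  /* 0 naf.m */ {-32.0,  6.0, 0.08, 0.0,   0.0,  1.0},
  /* 1 naf.h */ {-45.0, -6.0, 0.30, 3.5, -45.0, 12.0},
  /* 2 nap.m */ {-40.0,  5.0, 1.50, 0.0,   0.0,  1.0},
  /* 3 kdr.n */ {-30.0, 10.0, 0.60, 2.5, -30.0, 20.0},
  /* 4 ka.a  */ {-30.0,  8.0, 0.30, 0.0,   0.0,  1.0},
  /* 5 ka.b  */ {-75.0, -6.0, 12.0, 0.0,   0.0,  1.0},
  /* 6 kd.a  */ {-40.0, 10.0, 1.00, 0.0,   0.0,  1.0},
  /* 7 kd.b  */ {-70.0, -6.0, 120., 0.0,   0.0,  1.0},
  /* 8 fahp.w*/ { -5.0,  8.0, 1.50, 0.0,   0.0,  1.0},  // times Ca factor
  /* 9 h.q   */ {-82.0, -7.0, 50.0, 0.0,   0.0,  1.0},
  /*10 cat.m */ {-57.0,  6.2, 2.50, 0.0,   0.0,  1.0},
  /*11 cat.h */ {-81.0, -4.0, 40.0, 0.0,   0.0,  1.0},
  /*12 can.m */ {-25.0,  7.0, 1.50, 0.0,   0.0,  1.0},
  /*13 can.h */ {-50.0,-12.0, 80.0, 0.0,   0.0,  1.0},
  /*14 car.m */ {-25.0,  8.0, 4.00, 0.0,   0.0,  1.0},
  /*15 car.h */ {-40.0,-10.0, 60.0, 0.0,   0.0,  1.0},
  /*16 cal.m */ {-15.0,  6.0, 1.50, 0.0,   0.0,  1.0},
  /*17 sahp.q*/ {  0.0,  1.0, 60.0, 0.0,   0.0,  1.0}   // Ca-only gate; vhalf unused
};

static inline double gate_inf(const GateDef &g, double v) {
  return 1.0 / (1.0 + std::exp(-(v - g.vhalf) / g.k));
}
static inline double gate_tau(const GateDef &g, double v) {
  if (g.tauamp == 0.0) return g.tau0;
  return g.tau0 + g.tauamp / std::cosh((v - g.tauv) / g.taus);
}

// per-channel gate indices into the 18-gate state block
static const int CH_GATE1[N_CHANNELS] = {0, 2, 3, 4, 6, 8, 17, 9, 10, 12, 14, 16};
static const int CH_GATE2[N_CHANNELS] = {1,-1,-1, 5, 7,-1, -1,-1, 11, 13, 15, -1};
static const int CH_POW1[N_CHANNELS]  = {3, 1, 4, 1, 1, 1,  1, 1,  2,  2,  3,  2};
static const bool CH_IS_CA[N_CHANNELS] = {false,false,false,false,false,false,
                                          false,false,true,true,true,true};

static inline double ipow(double x, int p) {
  double r = x;
  for (int i = 1; i < p; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".simulate_cell_cpp")]]
List simulate_cell_cpp(IntegerVector parent,      // 0-based, -1 for root
                       NumericVector area_cm2,
                       NumericVector g_pas,       // S/cm2
                       double e_pas,
                       double cm_uf,              // uF/cm2
                       NumericVector g_ax,        // uS, coupling to parent
                       NumericMatrix dens,        // n x 12, S/cm2
                       NumericMatrix stim,        // k x 4: t0, t1, amp_nA, comp
                       double dt, double t_stop, double settle_ms,
                       int record,                // 0-based compartment
                       double v_init,
                       double e_na, double e_k, double e_h,
                       double ca0_mM, double cao_mM,
                       double ca_gain, double ca_tau) {
  const int n = parent.size();
  if (record < 0 || record >= n) stop("record site out of range");
  std::vector<double> v(n, v_init), cai(n, ca0_mM), eca(n);
  std::vector<double> cap(n);      // C/dt, uS
  for (int i = 0; i < n; ++i) {
    if (area_cm2[i] <= 0) stop("zero-area compartment");
    cap[i] = cm_uf * area_cm2[i] * 1e3 / dt;  // nF/ms = uS
  }

  // active channels per compartment
  std::vector<std::vector<int>> active(n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < N_CHANNELS; ++c)
      if (dens(i, c) > 0) active[i].push_back(c);

  // gate state: n x 18, initialised at steady state for v_init
  std::vector<double> g_state(n * N_VGATES);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < N_VGATES; ++g)
      g_state[i * N_VGATES + g] = gate_inf(GATES[g], v_init);
  // Ca-dependent gates start shut at resting Ca
  const double kd_fahp = 0.005, kd_sahp = 0.005;  // mM
  auto ca_act = [](double ca, double kd) {
    double r = (ca * ca) / (ca * ca + kd * kd);
    return r;
  };
  for (int i = 0; i < n; ++i) {
    g_state[i * N_VGATES + 8] *= ca_act(ca0_mM, kd_fahp);
    g_state[i * N_VGATES + 17] = ca_act(ca0_mM, kd_sahp);
    eca[i] = 13.35 * std::log(cao_mM / cai[i]);
  }

  const int n_settle = (int)std::round(settle_ms / dt);
  const int n_run = (int)std::round(t_stop / dt);
  NumericVector t_out(n_run + 1), v_out(n_run + 1);

  std::vector<double> diag(n), rhs(n), i_inj(n, 0.0);

  for (int step = -n_settle; step < n_run; ++step) {
    const double t_now = (step >= 0 ? step * dt : 0.0);
    if (step == 0) { t_out[0] = 0.0; v_out[0] = v[record]; }

    // stimulus for this step (active during [t0, t1), settle has none)
    std::fill(i_inj.begin(), i_inj.end(), 0.0);
    if (step >= 0) {
      for (int s = 0; s < stim.nrow(); ++s) {
        if (t_now >= stim(s, 0) && t_now < stim(s, 1)) {
          int c = (int)stim(s, 3);
          if (c < 0 || c >= n) stop("stimulus target out of range");
          i_inj[c] += stim(s, 2);
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      double *gs = &g_state[i * N_VGATES];

      // Ca pool from Ca-channel current densities (mA/cm2)
      double ica = 0.0;
      for (int c : active[i]) {
        if (!CH_IS_CA[c]) continue;
        double go = ipow(gs[CH_GATE1[c]], CH_POW1[c]);
        if (CH_GATE2[c] >= 0) go *= gs[CH_GATE2[c]];
        ica += dens(i, c) * go * (vi - eca[i]);
      }
      const double cinf = ca0_mM - ca_gain * ica * ca_tau;
      cai[i] += (cinf - cai[i]) * (1.0 - std::exp(-dt / ca_tau));
      if (cai[i] < 1e-6) cai[i] = 1e-6;
      eca[i] = 13.35 * std::log(cao_mM / cai[i]);

      // voltage-dependent gate updates (exponential, exact for frozen V)
      for (int c : active[i]) {
        int g1 = CH_GATE1[c], g2 = CH_GATE2[c];
        if (c == 5) {  // fahp: voltage gate scaled by Ca activation
          double xinf = gate_inf(GATES[8], vi) * ca_act(cai[i], kd_fahp);
          gs[8] += (xinf - gs[8]) * (1.0 - std::exp(-dt / gate_tau(GATES[8], vi)));
          continue;
        }
        if (c == 6) {  // sahp: pure Ca gate
          double xinf = ca_act(cai[i], kd_sahp);
          gs[17] += (xinf - gs[17]) * (1.0 - std::exp(-dt / GATES[17].tau0));
          continue;
        }
        double xinf = gate_inf(GATES[g1], vi);
        gs[g1] += (xinf - gs[g1]) * (1.0 - std::exp(-dt / gate_tau(GATES[g1], vi)));
        if (g2 >= 0) {
          xinf = gate_inf(GATES[g2], vi);
          gs[g2] += (xinf - gs[g2]) * (1.0 - std::exp(-dt / gate_tau(GATES[g2], vi)));
        }
      }

      // assemble diagonal and rhs (channel conductances frozen over the step)
      const double a6 = area_cm2[i] * 1e6;  // S/cm2 -> uS factor
      double gd = g_pas[i] * a6, ge = g_pas[i] * a6 * e_pas;
      for (int c : active[i]) {
        double go = ipow(gs[CH_GATE1[c]], CH_POW1[c]);
        if (CH_GATE2[c] >= 0) go *= gs[CH_GATE2[c]];
        const double gabs = dens(i, c) * go * a6;
        double e;
        if (CH_IS_CA[c]) e = eca[i];
        else if (c <= 1) e = e_na;       // naf, nap
        else if (c == 7) e = e_h;
        else e = e_k;                    // kdr, ka, kd, fahp, sahp
        gd += gabs; ge += gabs * e;
      }
      diag[i] = cap[i] + gd;
      rhs[i] = cap[i] * v[i] + ge + i_inj[i];
    }

    // axial terms and Hines solve (parent index < child index)
    for (int i = 1; i < n; ++i) {
      diag[i] += g_ax[i];
      diag[parent[i]] += g_ax[i];
    }
    for (int i = n - 1; i >= 1; --i) {
      const double f = g_ax[i] / diag[i];
      diag[parent[i]] -= f * g_ax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / diag[i];

    if (!std::isfinite(v[record]) || !std::isfinite(v[0]))
      stop("numerical failure (non-finite voltage) at t = %f ms", t_now);

    if (step >= 0) {
      t_out[step + 1] = (step + 1) * dt;
      v_out[step + 1] = v[record];
    }
  }

  return List::create(_["t_ms"] = t_out, _["v_mv"] = v_out,
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}
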
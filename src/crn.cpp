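// Courtemanche-Ramirez-Nattel (1998) human atrial cardiomyocyte model
// extended with a TASK-1 (K2P) background potassium current, plus a 1D
// monodomain cable built from the same cell kernel.
//
// Units: mV, ms, mM, pA/pF throughout; conductances nS/pF; Cm in pF.
// Integration: Rush-Larsen for the 15 Hodgkin-Huxley-type gates, forward
// Euler for membrane voltage and the five ionic concentrations.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// physical constants
static const double R_GAS = 8.3143;   // J mol^-1 K^-1
static const double TEMP  = 310.0;    // K
static const double FARAD = 96.4867;  // C mmol^-1

// cell compartment volumes (um^3)
static const double V_I   = 13668.0;
static const double V_UP  = 1109.52;
static const double V_REL = 96.48;

// Ca handling constants
static const double K_Q10    = 3.0;
static const double CMDN_MAX = 0.05,    TRPN_MAX = 0.07,   CSQN_MAX = 10.0;
static const double KM_CMDN  = 0.00238, KM_TRPN  = 0.0005, KM_CSQN  = 0.8;
static const double K_REL = 30.0, TAU_TR = 180.0;
static const double I_UP_MAX = 0.005, K_UP = 0.00092, CA_UP_MAX = 15.0;

// pump/exchanger constants
static const double KM_NA_I = 10.0, KM_K_O = 1.5;
static const double KM_NA = 87.5, KM_CA = 1.38, K_SAT = 0.1, GAMMA_NACA = 0.35;

// parameter vector layout (kept in step with crn_params() on the R side)
enum ParIdx {
  P_G_NA = 0, P_G_K1, P_G_TO, P_G_KR, P_G_KS, P_G_CAL, P_G_KUR,
  P_G_BNA, P_G_BCA, P_INAK_MAX, P_INACA_MAX, P_IPCA_MAX, P_G_K2P,
  P_K_O, P_NA_O, P_CA_O, P_CM, NPAR
};

// state vector layout
enum StIdx {
  S_V = 0, S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI, S_XR, S_XS,
  S_D, S_F, S_FCA, S_U, S_VG, S_W, S_NAI, S_KI, S_CAI, S_CAUP, S_CAREL,
  NSTATE
};

struct GateUpd { double inf; double tau; };

static inline double sq(double x) { return x * x; }
static inline double cube(double x) { return x * x * x; }

// TASK-1 background current: open (GHK-type) rectification expressed as a
// chord conductance; g_k2p is the chord conductance at 0 mV in nS/pF.
// phi(V) = u*(Ki - Ko*exp(-u))/(1 - exp(-u)), u = VF/RT; I = g*phi*(-EK)/(Ki-Ko)
static inline double ik2p_current_core(double v, double ko, double ki, double gk2p) {
  const double rtf = R_GAS * TEMP / FARAD;
  const double ek = rtf * std::log(ko / ki);
  const double u = v / rtf;
  double phi;
  if (std::fabs(u) < 1e-6) {
    phi = (ki - ko * std::exp(-u)) * (1.0 + 0.5 * u);
  } else {
    phi = u * (ki - ko * std::exp(-u)) / (1.0 - std::exp(-u));
  }
  return gk2p * phi * (-ek) / (ki - ko);
}

// All voltage/Ca-dependent gate kinetics. Returns inf and tau per gate.
static void gate_kinetics(double v, double cai, double fn, GateUpd g[15]) {
  double a, b;

  // m
  if (std::fabs(v + 47.13) < 1e-10) a = 3.2;
  else a = 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
  b = 0.08 * std::exp(-v / 11.0);
  g[0].inf = a / (a + b); g[0].tau = 1.0 / (a + b);

  // h
  if (v >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(v + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
  }
  g[1].inf = a / (a + b); g[1].tau = 1.0 / (a + b);

  // j
  if (v >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
        (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  g[2].inf = a / (a + b); g[2].tau = 1.0 / (a + b);

  // oa
  a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
  g[3].tau = 1.0 / ((a + b) * K_Q10);
  g[3].inf = 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54));

  // oi
  a = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
  g[4].tau = 1.0 / ((a + b) * K_Q10);
  g[4].inf = 1.0 / (1.0 + std::exp((v + 43.1) / 5.3));

  // ua
  a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
  g[5].tau = 1.0 / ((a + b) * K_Q10);
  g[5].inf = 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6));

  // ui
  a = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
  b = std::exp((v - 158.0) / 16.0);
  g[6].tau = 1.0 / ((a + b) * K_Q10);
  g[6].inf = 1.0 / (1.0 + std::exp((v - 99.45) / 27.48));

  // xr
  if (std::fabs(v + 14.1) < 1e-10) a = 0.0015;
  else a = 0.0003 * (v + 14.1) / (1.0 - std::exp(-(v + 14.1) / 5.0));
  if (std::fabs(v - 3.3328) < 1e-10) b = 3.7862e-4;
  else b = 7.3898e-5 * (v - 3.3328) / (std::exp((v - 3.3328) / 5.1237) - 1.0);
  g[7].tau = 1.0 / (a + b);
  g[7].inf = 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5));

  // xs
  if (std::fabs(v - 19.9) < 1e-10) a = 6.8e-4;
  else a = 4e-5 * (v - 19.9) / (1.0 - std::exp(-(v - 19.9) / 17.0));
  if (std::fabs(v - 19.9) < 1e-10) b = 3.15e-4;
  else b = 3.5e-5 * (v - 19.9) / (std::exp((v - 19.9) / 9.0) - 1.0);
  g[8].tau = 0.5 / (a + b);
  g[8].inf = 1.0 / std::sqrt(1.0 + std::exp(-(v - 19.9) / 12.7));

  // d
  if (std::fabs(v + 10.0) < 1e-10) {
    g[9].tau = 1.0 / (6.24 * 0.07);
  } else {
    double e = std::exp(-(v + 10.0) / 6.24);
    g[9].tau = (1.0 - e) / (0.035 * (v + 10.0) * (1.0 + e));
  }
  g[9].inf = 1.0 / (1.0 + std::exp(-(v + 10.0) / 8.0));

  // f
  g[10].tau = 9.0 / (0.0197 * std::exp(-sq(0.0337) * sq(v + 10.0)) + 0.02);
  g[10].inf = 1.0 / (1.0 + std::exp((v + 28.0) / 6.9));

  // f_Ca
  g[11].tau = 2.0;
  g[11].inf = 1.0 / (1.0 + cai / 0.00035);

  // u (SR release activation), driven by Fn
  g[12].tau = 8.0;
  g[12].inf = 1.0 / (1.0 + std::exp(-(fn - 3.4175e-13) / 13.67e-16));

  // v (SR release inactivation)
  g[13].tau = 1.91 + 2.09 / (1.0 + std::exp(-(fn - 3.4175e-13) / 13.67e-16));
  g[13].inf = 1.0 - 1.0 / (1.0 + std::exp(-(fn - 6.835e-14) / 13.67e-16));

  // w
  if (std::fabs(v - 7.9) < 1e-10) {
    g[14].tau = 6.0 / (5.0 * 1.3);
  } else {
    double e = std::exp(-(v - 7.9) / 5.0);
    g[14].tau = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (v - 7.9));
  }
  g[14].inf = 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0));
}

// -------------------------------------------------------------------------
// Voltage lookup tables. All purely voltage-dependent kinetics and current
// factors are tabulated on a fine grid and linearly interpolated, the
// standard acceleration for CRN-class reaction-diffusion solvers. Tables
// are rebuilt per integration call (they depend on dt and Na_o).
// -------------------------------------------------------------------------
enum VtCol {
  // steady states and Rush-Larsen multipliers exp(-dt/tau) for the 12
  // purely voltage-dependent gates (m h j oa oi ua ui xr xs d f w)
  VT_INF0 = 0, VT_RL0 = 12,
  VT_IK1F = 24, VT_GKURF, VT_IKRF, VT_FNAK, VT_NACA_E1, VT_NACA_E2,
  VT_K2P_A, VT_K2P_B, VT_NCOL
};
static const int VGATE_K[12] = { 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 14 };
static const int VGATE_S[12] = { S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI,
                                 S_XR, S_XS, S_D, S_F, S_W };

struct VTab {
  double vmin, step, inv;
  int n;
  double rl_fca, rl_u;      // constant-tau gates
  std::vector<double> data; // n rows x VT_NCOL
};

static void build_vtab(VTab& T, const double* p, double dt) {
  T.vmin = -150.0; T.step = 0.05; T.inv = 1.0 / T.step;
  T.n = (int)std::lround((100.0 - T.vmin) / T.step) + 1;
  T.data.assign((std::size_t)T.n * VT_NCOL, 0.0);
  T.rl_fca = std::exp(-dt / 2.0);
  T.rl_u = std::exp(-dt / 8.0);
  const double rtf = R_GAS * TEMP / FARAD;
  const double sigma = (std::exp(p[P_NA_O] / 67.3) - 1.0) / 7.0;
  GateUpd g[15];
  for (int i = 0; i < T.n; ++i) {
    const double v = T.vmin + i * T.step;
    double* row = &T.data[(std::size_t)i * VT_NCOL];
    gate_kinetics(v, 2e-4, 0.0, g);   // cai/fn placeholders: those gates
                                      // are handled analytically
    for (int k = 0; k < 12; ++k) {
      row[VT_INF0 + k] = g[VGATE_K[k]].inf;
      row[VT_RL0 + k] = std::exp(-dt / g[VGATE_K[k]].tau);
    }
    row[VT_IK1F] = 1.0 / (1.0 + std::exp(0.07 * (v + 80.0)));
    row[VT_GKURF] = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
    row[VT_IKRF] = 1.0 / (1.0 + std::exp((v + 15.0) / 22.4));
    row[VT_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                          0.0365 * sigma * std::exp(-v / rtf));
    row[VT_NACA_E1] = std::exp(GAMMA_NACA * v / rtf);
    row[VT_NACA_E2] = std::exp((GAMMA_NACA - 1.0) * v / rtf);
    // GHK flux split phi(V) = Ki*A(V) - Ko*B(V)
    const double u = v / rtf;
    if (std::fabs(u) < 1e-6) {
      row[VT_K2P_A] = 1.0 + 0.5 * u;
      row[VT_K2P_B] = (1.0 + 0.5 * u) * std::exp(-u);
    } else {
      row[VT_K2P_A] = u / (1.0 - std::exp(-u));
      row[VT_K2P_B] = u * std::exp(-u) / (1.0 - std::exp(-u));
    }
  }
}

// tabulated reaction step; same semantics as reaction_step()
static inline double reaction_step_tab(double* y, const double* p, double dt,
                                       const VTab& T) {
  const double rtf = R_GAS * TEMP / FARAD;
  const double v = y[S_V];
  const double nai = y[S_NAI], ki = y[S_KI], cai = y[S_CAI];
  const double nao = p[P_NA_O], ko = p[P_K_O], cao = p[P_CA_O];
  const double cm = p[P_CM];

  double pos = (v - T.vmin) * T.inv;
  if (pos < 0.0) pos = 0.0;
  if (pos > T.n - 1.001) pos = T.n - 1.001;
  const int i0 = (int)pos;
  const double w = pos - i0;
  const double* r0 = &T.data[(std::size_t)i0 * VT_NCOL];
  const double* r1 = r0 + VT_NCOL;
#define LERP(c) (r0[c] + w * (r1[c] - r0[c]))

  const double ena = rtf * std::log(nao / nai);
  const double ek  = rtf * std::log(ko / ki);
  const double eca = 0.5 * rtf * std::log(cao / cai);

  const double ina = p[P_G_NA] * cube(y[S_M]) * y[S_H] * y[S_J] * (v - ena);
  const double ik1 = p[P_G_K1] * (v - ek) * LERP(VT_IK1F);
  const double ito = p[P_G_TO] * cube(y[S_OA]) * y[S_OI] * (v - ek);
  const double ikur = p[P_G_KUR] * LERP(VT_GKURF) * cube(y[S_UA]) * y[S_UI] *
                      (v - ek);
  const double ikr = p[P_G_KR] * y[S_XR] * (v - ek) * LERP(VT_IKRF);
  const double iks = p[P_G_KS] * sq(y[S_XS]) * (v - ek);
  const double ical = p[P_G_CAL] * y[S_D] * y[S_F] * y[S_FCA] * (v - 65.0);
  const double ipca = p[P_IPCA_MAX] * cai / (0.0005 + cai);
  const double inak = p[P_INAK_MAX] * LERP(VT_FNAK) /
                      (1.0 + std::pow(KM_NA_I / nai, 1.5)) * ko / (ko + KM_K_O);
  const double e2 = LERP(VT_NACA_E2);
  const double inaca = p[P_INACA_MAX] *
      (LERP(VT_NACA_E1) * cube(nai) * cao - e2 * cube(nao) * cai) /
      ((cube(KM_NA) + cube(nao)) * (KM_CA + cao) * (1.0 + K_SAT * e2));
  const double ibna = p[P_G_BNA] * (v - ena);
  const double ibca = p[P_G_BCA] * (v - eca);
  const double ik2p = p[P_G_K2P] * (ki * LERP(VT_K2P_A) - ko * LERP(VT_K2P_B)) *
                      (-ek) / (ki - ko);

  // SR fluxes
  const double irel = K_REL * sq(y[S_U]) * y[S_VG] * y[S_W] *
                      (y[S_CAREL] - y[S_CAI]);
  const double itr = (y[S_CAUP] - y[S_CAREL]) / TAU_TR;
  const double iup = I_UP_MAX / (1.0 + K_UP / cai);
  const double iupleak = I_UP_MAX * y[S_CAUP] / CA_UP_MAX;
  const double fn = 1e-12 * V_REL * irel -
                    1e-12 / (2.0 * FARAD) * (0.5 * ical * cm - 0.2 * inaca * cm);

  // voltage-dependent gates from the table
  for (int k = 0; k < 12; ++k) {
    const int s = VGATE_S[k];
    const double inf = LERP(VT_INF0 + k);
    y[s] = inf + (y[s] - inf) * LERP(VT_RL0 + k);
  }
  // Ca/Fn-dependent gates analytically
  {
    const double inf = 1.0 / (1.0 + cai / 0.00035);
    y[S_FCA] = inf + (y[S_FCA] - inf) * T.rl_fca;
    const double uinf = 1.0 / (1.0 + std::exp(-(fn - 3.4175e-13) / 13.67e-16));
    y[S_U] = uinf + (y[S_U] - uinf) * T.rl_u;
    const double tauv = 1.91 + 2.09 * uinf;
    const double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(fn - 6.835e-14) / 13.67e-16));
    y[S_VG] = vinf + (y[S_VG] - vinf) * std::exp(-dt / tauv);
  }
#undef LERP

  // concentrations (Euler)
  const double f_vi = cm / (FARAD * V_I);
  y[S_NAI] += dt * (-3.0 * inak - 3.0 * inaca - ibna - ina) * f_vi;
  y[S_KI] += dt * (2.0 * inak - ik1 - ito - ikur - ikr - iks - ik2p) * f_vi;
  const double b1 = (2.0 * inaca - ipca - ical - ibca) * cm /
                    (2.0 * FARAD * V_I) +
                    (V_UP * (iupleak - iup) + irel * V_REL) / V_I;
  const double b2 = 1.0 + TRPN_MAX * KM_TRPN / sq(cai + KM_TRPN) +
                    CMDN_MAX * KM_CMDN / sq(cai + KM_CMDN);
  y[S_CAI] += dt * b1 / b2;
  y[S_CAUP] += dt * (iup - iupleak - itr * V_REL / V_UP);
  y[S_CAREL] += dt * (itr - irel) /
                (1.0 + CSQN_MAX * KM_CSQN / sq(y[S_CAREL] + KM_CSQN));

  return ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak + inaca +
         ibna + ibca + ik2p;
}

struct Currents {
  double ina, ik1, ito, ikur, ikr, iks, ical, ipca, inak, inaca, ibna, ibca, ik2p;
  double total() const {
    return ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak + inaca +
           ibna + ibca + ik2p;
  }
};

static void compute_currents(const double* y, const double* p, Currents& c) {
  const double rtf = R_GAS * TEMP / FARAD;
  const double v = y[S_V];
  const double nai = y[S_NAI], ki = y[S_KI], cai = y[S_CAI];
  const double nao = p[P_NA_O], ko = p[P_K_O], cao = p[P_CA_O];

  const double ena = rtf * std::log(nao / nai);
  const double ek  = rtf * std::log(ko / ki);
  const double eca = 0.5 * rtf * std::log(cao / cai);

  c.ina = p[P_G_NA] * cube(y[S_M]) * y[S_H] * y[S_J] * (v - ena);
  c.ik1 = p[P_G_K1] * (v - ek) / (1.0 + std::exp(0.07 * (v + 80.0)));
  c.ito = p[P_G_TO] * cube(y[S_OA]) * y[S_OI] * (v - ek);
  const double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
  c.ikur = p[P_G_KUR] * gkur * cube(y[S_UA]) * y[S_UI] * (v - ek);
  c.ikr = p[P_G_KR] * y[S_XR] * (v - ek) / (1.0 + std::exp((v + 15.0) / 22.4));
  c.iks = p[P_G_KS] * sq(y[S_XS]) * (v - ek);
  c.ical = p[P_G_CAL] * y[S_D] * y[S_F] * y[S_FCA] * (v - 65.0);
  c.ipca = p[P_IPCA_MAX] * cai / (0.0005 + cai);

  const double sigma = (std::exp(nao / 67.3) - 1.0) / 7.0;
  const double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                             0.0365 * sigma * std::exp(-v / rtf));
  c.inak = p[P_INAK_MAX] * fnak / (1.0 + std::pow(KM_NA_I / nai, 1.5)) *
           ko / (ko + KM_K_O);

  const double ef1 = std::exp(GAMMA_NACA * v / rtf);
  const double ef2 = std::exp((GAMMA_NACA - 1.0) * v / rtf);
  c.inaca = p[P_INACA_MAX] *
            (ef1 * cube(nai) * cao - ef2 * cube(nao) * cai) /
            ((cube(KM_NA) + cube(nao)) * (KM_CA + cao) * (1.0 + K_SAT * ef2));

  c.ibna = p[P_G_BNA] * (v - ena);
  c.ibca = p[P_G_BCA] * (v - eca);
  c.ik2p = ik2p_current_core(v, ko, ki, p[P_G_K2P]);
}

// one reaction step: Rush-Larsen gates + Euler concentrations; returns total
// ionic current (pA/pF) evaluated at the step's start, which the caller uses
// to advance V.
static inline double reaction_step(double* y, const double* p, double dt) {
  Currents c;
  compute_currents(y, p, c);
  const double cm = p[P_CM];

  // SR fluxes
  const double irel = K_REL * sq(y[S_U]) * y[S_VG] * y[S_W] * (y[S_CAREL] - y[S_CAI]);
  const double itr = (y[S_CAUP] - y[S_CAREL]) / TAU_TR;
  const double iup = I_UP_MAX / (1.0 + K_UP / y[S_CAI]);
  const double iupleak = I_UP_MAX * y[S_CAUP] / CA_UP_MAX;
  const double fn = 1e-12 * V_REL * irel -
                    1e-12 / (2.0 * FARAD) * (0.5 * c.ical * cm - 0.2 * c.inaca * cm);

  GateUpd g[15];
  gate_kinetics(y[S_V], y[S_CAI], fn, g);
  static const int gate_idx[15] = { S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI,
                                    S_XR, S_XS, S_D, S_F, S_FCA, S_U, S_VG, S_W };
  for (int k = 0; k < 15; ++k) {
    const int i = gate_idx[k];
    y[i] = g[k].inf + (y[i] - g[k].inf) * std::exp(-dt / g[k].tau);
  }

  // concentrations (Euler)
  const double f_vi = cm / (FARAD * V_I);
  const double dnai = (-3.0 * c.inak - 3.0 * c.inaca - c.ibna - c.ina) * f_vi;
  const double dki = (2.0 * c.inak - c.ik1 - c.ito - c.ikur - c.ikr - c.iks -
                      c.ik2p) * f_vi;
  const double b1 = (2.0 * c.inaca - c.ipca - c.ical - c.ibca) * cm /
                    (2.0 * FARAD * V_I) +
                    (V_UP * (iupleak - iup) + irel * V_REL) / V_I;
  const double b2 = 1.0 + TRPN_MAX * KM_TRPN / sq(y[S_CAI] + KM_TRPN) +
                    CMDN_MAX * KM_CMDN / sq(y[S_CAI] + KM_CMDN);
  const double dcaup = iup - iupleak - itr * V_REL / V_UP;
  const double dcarel = (itr - irel) /
                        (1.0 + CSQN_MAX * KM_CSQN / sq(y[S_CAREL] + KM_CSQN));

  y[S_NAI] += dt * dnai;
  y[S_KI] += dt * dki;
  y[S_CAI] += dt * b1 / b2;
  y[S_CAUP] += dt * dcaup;
  y[S_CAREL] += dt * dcarel;

  return c.total();
}

// stimulus bookkeeping: amplitude > 0 depolarizes (enters the voltage update
// as a negative contribution to the summed current)
static inline double stim_at(double t, const std::vector<double>& starts,
                             double dur, double amp, std::size_t& ptr) {
  while (ptr < starts.size() && t >= starts[ptr] + dur) ++ptr;
  if (ptr < starts.size() && t >= starts[ptr] && t < starts[ptr] + dur)
    return -amp;
  return 0.0;
}

// [[Rcpp::export]]
List crn_rhs_cpp(NumericVector state, NumericVector params, double i_stim) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  const double* y = state.begin();
  const double* p = params.begin();
  Currents c;
  compute_currents(y, p, c);
  const double cm = p[P_CM];

  const double irel = K_REL * sq(y[S_U]) * y[S_VG] * y[S_W] * (y[S_CAREL] - y[S_CAI]);
  const double itr = (y[S_CAUP] - y[S_CAREL]) / TAU_TR;
  const double iup = I_UP_MAX / (1.0 + K_UP / y[S_CAI]);
  const double iupleak = I_UP_MAX * y[S_CAUP] / CA_UP_MAX;
  const double fn = 1e-12 * V_REL * irel -
                    1e-12 / (2.0 * FARAD) * (0.5 * c.ical * cm - 0.2 * c.inaca * cm);

  GateUpd g[15];
  gate_kinetics(y[S_V], y[S_CAI], fn, g);

  NumericVector dy(NSTATE);
  dy[S_V] = -(c.total() + i_stim);
  static const int gate_idx[15] = { S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI,
                                    S_XR, S_XS, S_D, S_F, S_FCA, S_U, S_VG, S_W };
  for (int k = 0; k < 15; ++k) {
    const int i = gate_idx[k];
    dy[i] = (g[k].inf - y[i]) / g[k].tau;
  }
  const double f_vi = cm / (FARAD * V_I);
  dy[S_NAI] = (-3.0 * c.inak - 3.0 * c.inaca - c.ibna - c.ina) * f_vi;
  dy[S_KI] = (2.0 * c.inak - c.ik1 - c.ito - c.ikur - c.ikr - c.iks - c.ik2p) * f_vi;
  const double b1 = (2.0 * c.inaca - c.ipca - c.ical - c.ibca) * cm /
                    (2.0 * FARAD * V_I) +
                    (V_UP * (iupleak - iup) + irel * V_REL) / V_I;
  const double b2 = 1.0 + TRPN_MAX * KM_TRPN / sq(y[S_CAI] + KM_TRPN) +
                    CMDN_MAX * KM_CMDN / sq(y[S_CAI] + KM_CMDN);
  dy[S_CAI] = b1 / b2;
  dy[S_CAUP] = iup - iupleak - itr * V_REL / V_UP;
  dy[S_CAREL] = (itr - irel) /
                (1.0 + CSQN_MAX * KM_CSQN / sq(y[S_CAREL] + KM_CSQN));

  return List::create(
    _["dy"] = dy,
    _["currents"] = NumericVector::create(
      _["i_na"] = c.ina, _["i_k1"] = c.ik1, _["i_to"] = c.ito,
      _["i_kur"] = c.ikur, _["i_kr"] = c.ikr, _["i_ks"] = c.iks,
      _["i_cal"] = c.ical, _["i_pca"] = c.ipca, _["i_nak"] = c.inak,
      _["i_naca"] = c.inaca, _["i_bna"] = c.ibna, _["i_bca"] = c.ibca,
      _["i_k2p"] = c.ik2p));
}

// [[Rcpp::export]]
double ik2p_current_cpp(double vm, double k_o, double k_i, double g_k2p) {
  return ik2p_current_core(vm, k_o, k_i, g_k2p);
}

// [[Rcpp::export]]
List crn_integrate_cpp(NumericVector state0, NumericVector params,
                       double duration, double dt,
                       NumericVector stim_starts, double stim_dur,
                       double stim_amp, double sample_dt, double record_from) {
  if (state0.size() != NSTATE) stop("state0 must have %d entries", NSTATE);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];
  const double* p = params.begin();

  const long n_steps = (long)std::llround(duration / dt);
  const long sample_every = std::max(1L, (long)std::llround(sample_dt / dt));
  std::vector<double> starts(stim_starts.begin(), stim_starts.end());
  std::size_t sptr = 0;

  VTab tab;
  build_vtab(tab, p, dt);

  std::vector<double> ts, vs;
  ts.reserve(n_steps / sample_every + 2);
  vs.reserve(n_steps / sample_every + 2);

  bool aborted = false;
  double abort_t = NA_REAL;
  for (long k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    if (t >= record_from && (k % sample_every) == 0) {
      ts.push_back(t);
      vs.push_back(y[S_V]);
    }
    const double istim = stim_at(t, starts, stim_dur, stim_amp, sptr);
    const double iion = reaction_step_tab(y, p, dt, tab);
    y[S_V] += dt * (-(iion + istim));
    if (!std::isfinite(y[S_V]) || std::fabs(y[S_V]) > 200.0) {
      aborted = true;
      abort_t = t;
      break;
    }
  }

  NumericVector yfin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yfin[i] = y[i];
  return List::create(
    _["time"] = NumericVector(ts.begin(), ts.end()),
    _["vm"] = NumericVector(vs.begin(), vs.end()),
    _["state"] = yfin,
    _["aborted"] = aborted,
    _["abort_time"] = abort_t);
}

// 1D monodomain cable with zero-flux ends and Strang splitting
// (half diffusion, reaction, half diffusion). Homogeneous parameters.
// Activation per cell = instant of max dV/dt while the upstroke passes
// from below -60 mV up through -40 mV (tracked for 5 ms after crossing).
// [[Rcpp::export]]
List cable_integrate_cpp(NumericMatrix state0, NumericVector params,
                         double diff_coef, double dx,
                         double duration, double dt,
                         NumericVector stim_starts, double stim_dur,
                         double stim_amp, int stim_from, int stim_to,
                         IntegerVector record_cells, double sample_dt,
                         double record_from, bool reaction_on) {
  if (state0.nrow() != NSTATE) stop("state0 must have %d rows", NSTATE);
  const int nc = state0.ncol();
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  const double r_half = diff_coef * (dt / 2.0) / (dx * dx);
  if (diff_coef * dt / (dx * dx) > 0.5)
    stop("diffusion stability violated: D*dt/dx^2 = %g > 0.5",
         diff_coef * dt / (dx * dx));
  if (stim_from < 0 || stim_to >= nc || stim_from > stim_to)
    stop("invalid stimulated cell range");

  std::vector<double> Y(NSTATE * (std::size_t)nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < NSTATE; ++i) Y[c * NSTATE + i] = state0(i, c);

  const long n_steps = (long)std::llround(duration / dt);
  const long sample_every = std::max(1L, (long)std::llround(sample_dt / dt));
  std::vector<double> starts(stim_starts.begin(), stim_starts.end());
  std::size_t sptr = 0;

  VTab tab;
  build_vtab(tab, params.begin(), dt);

  const int nrec = record_cells.size();
  std::vector<std::vector<double>> traces(nrec);
  std::vector<double> ts;

  // activation tracking
  std::vector<std::vector<double>> act(nc);
  std::vector<int> phase(nc, 0);          // 0 rest, 1 tracking, 2 activated
  std::vector<double> best_dvdt(nc, 0.0), best_t(nc, 0.0), track_until(nc, 0.0);
  std::vector<double> vprev(nc), vnew(nc);

  bool aborted = false;
  double abort_t = NA_REAL;

  for (long k = 0; k < n_steps && !aborted; ++k) {
    const double t = k * dt;
    if (t >= record_from && (k % sample_every) == 0) {
      ts.push_back(t);
      for (int r = 0; r < nrec; ++r)
        traces[r].push_back(Y[record_cells[r] * NSTATE + S_V]);
    }
    for (int c = 0; c < nc; ++c) vprev[c] = Y[c * NSTATE + S_V];

    // half diffusion
    for (int c = 0; c < nc; ++c) {
      const double vl = vprev[c > 0 ? c - 1 : 0];
      const double vr = vprev[c < nc - 1 ? c + 1 : nc - 1];
      vnew[c] = vprev[c] + r_half * (vl - 2.0 * vprev[c] + vr);
    }
    for (int c = 0; c < nc; ++c) Y[c * NSTATE + S_V] = vnew[c];

    // reaction
    const double istim = stim_at(t, starts, stim_dur, stim_amp, sptr);
    if (reaction_on) {
      for (int c = 0; c < nc; ++c) {
        double* y = &Y[c * NSTATE];
        const double is = (c >= stim_from && c <= stim_to) ? istim : 0.0;
        const double iion = reaction_step_tab(y, params.begin(), dt, tab);
        y[S_V] += dt * (-(iion + is));
        if (!std::isfinite(y[S_V]) || std::fabs(y[S_V]) > 200.0) {
          aborted = true;
          abort_t = t;
        }
      }
    } else if (istim != 0.0) {
      for (int c = stim_from; c <= stim_to; ++c)
        Y[c * NSTATE + S_V] += dt * (-istim);
    }

    // half diffusion
    for (int c = 0; c < nc; ++c) vnew[c] = Y[c * NSTATE + S_V];
    for (int c = 0; c < nc; ++c) {
      const double vl = vnew[c > 0 ? c - 1 : 0];
      const double vr = vnew[c < nc - 1 ? c + 1 : nc - 1];
      Y[c * NSTATE + S_V] = vnew[c] + r_half * (vl - 2.0 * vnew[c] + vr);
    }

    // activation detection on the full step increment
    for (int c = 0; c < nc; ++c) {
      const double v = Y[c * NSTATE + S_V];
      const double dvdt = (v - vprev[c]) / dt;
      switch (phase[c]) {
      case 0:
        if (v >= -40.0) {
          phase[c] = 1;
          best_dvdt[c] = dvdt;
          best_t[c] = t;
          track_until[c] = t + 5.0;
        }
        break;
      case 1:
        if (dvdt > best_dvdt[c]) { best_dvdt[c] = dvdt; best_t[c] = t; }
        if (t >= track_until[c]) {
          act[c].push_back(best_t[c]);
          phase[c] = 2;
        }
        break;
      case 2:
        if (v < -60.0) phase[c] = 0;
        break;
      }
    }
  }
  // flush a pending upstroke at end of run
  for (int c = 0; c < nc; ++c)
    if (phase[c] == 1) act[c].push_back(best_t[c]);

  NumericMatrix yfin(NSTATE, nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < NSTATE; ++i) yfin(i, c) = Y[c * NSTATE + i];

  List act_out(nc);
  for (int c = 0; c < nc; ++c)
    act_out[c] = NumericVector(act[c].begin(), act[c].end());

  List tr_out(nrec);
  for (int r = 0; r < nrec; ++r)
    tr_out[r] = NumericVector(traces[r].begin(), traces[r].end());

  return List::create(
    _["time"] = NumericVector(ts.begin(), ts.end()),
    _["traces"] = tr_out,
    _["activations"] = act_out,
    _["state"] = yfin,
    _["aborted"] = aborted,
    _["abort_time"] = abort_t);
}
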
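// Ionic membrane kinetics and monodomain tissue integration.
//
// Myocytes follow the Courtemanche-Ramirez-Nattel (CRN) human atrial action
// potential model, extended with the acetylcholine-activated inward-rectifier
// potassium current IKACh (Kneller-type formulation).  Fibroblasts follow the
// MacCannell active-fibroblast model (four membrane currents, two gates).
//
// Two evaluation paths are provided:
//   * exact right-hand sides (crn_rhs_cpp / fib_rhs_cpp), used by tests and
//     as a deSolve-compatible oracle;
//   * a fast fixed/dual-step integrator (Rush-Larsen for voltage gates with
//     precomputed rate tables, forward Euler elsewhere) used for single-cell
//     pacing and tissue simulation.
//
// Units: mV, ms, mM, pA/pF.  Diffusion coefficients cm^2/ms on lattice edges.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// CRN model constants
// ---------------------------------------------------------------------------
static const double Rgas = 8.3143;       // J/(mol K)
static const double Temp = 310.0;        // K
static const double Frdy = 96.4867;      // C/mmol
static const double RTF  = Rgas * Temp / Frdy;   // mV
static const double Cm   = 100.0;        // pF

static const double V_i   = 13668.0;     // um^3
static const double V_up  = 1109.52;
static const double V_rel = 96.48;

static const double K_o  = 5.4;          // mM
static const double Na_o = 140.0;
static const double Ca_o = 1.8;

static const double g_Na   = 7.8;        // nS/pF
static const double g_K1   = 0.09;
static const double g_to   = 0.1652;
static const double g_Kr   = 0.029411765;
static const double g_Ks   = 0.12941176;
static const double g_CaL  = 0.12375;
static const double g_B_Na = 0.0006744375;
static const double g_B_Ca = 0.001131;

static const double i_NaK_max = 0.59933874;
static const double Km_Na_i   = 10.0;
static const double Km_K_o    = 1.5;
static const double I_NaCa_max = 1600.0;
static const double K_mNa  = 87.5;
static const double K_mCa  = 1.38;
static const double K_sat  = 0.1;
static const double gama   = 0.35;
static const double i_CaP_max = 0.275;

static const double K_rel  = 30.0;
static const double tau_tr = 180.0;
static const double I_up_max = 0.005;
static const double K_up     = 0.00092;
static const double Ca_up_max = 15.0;

static const double CMDN_max = 0.05;
static const double TRPN_max = 0.07;
static const double CSQN_max = 10.0;
static const double Km_CMDN  = 0.00238;
static const double Km_TRPN  = 0.0005;
static const double Km_CSQN  = 0.8;

static const double K_Q10 = 3.0;

// IKACh (Kneller-type): I = g_dose(ACh) * (c1 + c2/(1+exp((V+vh)/vs))) * (V-EK)
static const double KACH_C1 = 0.0517;
static const double KACH_C2 = 0.4516;
static const double KACH_VH = 59.53;
static const double KACH_VS = 17.18;
static const double KACH_GMAX = 1.8;
static const double KACH_KD   = 9.13652;
static const double KACH_HILL = 0.477811;

// MacCannell fibroblast constants
static const double FIB_GKV   = 0.25;     // nS/pF
static const double FIB_GK1   = 0.4822;
static const double FIB_GBNA  = 0.0095;
static const double FIB_INAK  = 2.002;
static const double FIB_KMK   = 1.0;
static const double FIB_KMNA  = 11.0;
static const double FIB_VREV  = -150.0;
static const double FIB_B     = -200.0;
static const double FIB_KI    = 129.4349;
static const double FIB_NAI   = 8.5547;
static const double FIB_CM    = 6.3;      // pF (myocyte: 100 pF)

// state layout (myocyte): 21 doubles
enum { iV=0, iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS, iD, iF, iFCA,
       iU, iVG, iW, iNAI, iKI, iCAI, iCAUP, iCAREL, NSTATE };
// state slots of the 12 voltage gates handled by the rate table
// (m h j oa oi ua ui xr xs d f are contiguous; w is not)
static const int GATE_SLOT[12] = { iM, iH, iJ, iOA, iOI, iUA, iUI,
                                   iXR, iXS, iD, iF, iW };
// fibroblast reuses slots: iV, iM->r gate, iH->s gate

// [[Rcpp::export]]
double ikach_dose_factor_cpp(double ach) {
  if (ach < 0) stop("ACh concentration must be non-negative");
  if (ach == 0) return 0.0;
  return KACH_GMAX / (1.0 + KACH_KD / std::pow(ach, KACH_HILL));
}

// [[Rcpp::export]]
double ikach_cpp(double vm, double ach, double ek) {
  double g = ikach_dose_factor_cpp(ach);
  double vfac = KACH_C1 + KACH_C2 / (1.0 + std::exp((vm + KACH_VH) / KACH_VS));
  return g * vfac * (vm - ek);
}

static inline double safe_div(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

// exact CRN right-hand side; scales = (gto, gCaL, gKur, gK1), dach = dose factor
static void crn_rhs(const double *y, double *dy,
                    double sgto, double sgcal, double sgkur, double sgk1,
                    double dach, double istim, double *iion_out) {
  const double V = y[iV];
  const double E_Na = RTF * std::log(Na_o / y[iNAI]);
  const double E_K  = RTF * std::log(K_o  / y[iKI]);
  const double E_Ca = 0.5 * RTF * std::log(Ca_o / y[iCAI]);

  const double i_Na = g_Na * y[iM]*y[iM]*y[iM] * y[iH] * y[iJ] * (V - E_Na);
  const double i_K1 = sgk1 * g_K1 * (V - E_K) / (1.0 + std::exp(0.07*(V+80.0)));
  const double i_to = sgto * g_to * y[iOA]*y[iOA]*y[iOA] * y[iOI] * (V - E_K);
  const double g_Kur = 0.005 + 0.05 / (1.0 + std::exp(-(V-15.0)/13.0));
  const double i_Kur = sgkur * g_Kur * y[iUA]*y[iUA]*y[iUA] * y[iUI] * (V - E_K);
  const double i_Kr = g_Kr * y[iXR] * (V - E_K) / (1.0 + std::exp((V+15.0)/22.4));
  const double i_Ks = g_Ks * y[iXS]*y[iXS] * (V - E_K);
  const double i_CaL = sgcal * g_CaL * y[iD] * y[iF] * y[iFCA] * (V - 65.0);
  const double i_CaP = i_CaP_max * y[iCAI] / (0.0005 + y[iCAI]);
  const double sigma = (std::exp(Na_o/67.3) - 1.0) / 7.0;
  const double f_NaK = 1.0 / (1.0 + 0.1245*std::exp(-0.1*V/RTF)
                              + 0.0365*sigma*std::exp(-V/RTF));
  const double i_NaK = i_NaK_max * f_NaK *
    (1.0/(1.0+std::pow(Km_Na_i/y[iNAI],1.5))) * (K_o/(K_o+Km_K_o));
  const double e1 = std::exp(gama*V/RTF);
  const double e2 = std::exp((gama-1.0)*V/RTF);
  const double i_NaCa = I_NaCa_max *
    (e1*y[iNAI]*y[iNAI]*y[iNAI]*Ca_o - e2*Na_o*Na_o*Na_o*y[iCAI]) /
    ((K_mNa*K_mNa*K_mNa + Na_o*Na_o*Na_o)*(K_mCa + Ca_o)*(1.0 + K_sat*e2));
  const double i_B_Na = g_B_Na * (V - E_Na);
  const double i_B_Ca = g_B_Ca * (V - E_Ca);
  const double kach_vfac = KACH_C1 + KACH_C2/(1.0 + std::exp((V+KACH_VH)/KACH_VS));
  const double i_KACh = dach * kach_vfac * (V - E_K);

  // SR calcium handling
  const double i_rel = K_rel * y[iU]*y[iU] * y[iVG] * y[iW] * (y[iCAREL] - y[iCAI]);
  const double i_tr  = (y[iCAUP] - y[iCAREL]) / tau_tr;
  const double i_up  = I_up_max / (1.0 + K_up / y[iCAI]);
  const double i_up_leak = I_up_max * y[iCAUP] / Ca_up_max;

  const double Fn = 1000.0*(1e-15*V_rel*i_rel
                    - (1e-15/(2.0*Frdy))*(0.5*i_CaL*Cm - 0.2*i_NaCa*Cm));

  // gating rates
  double a, b;
  // m
  a = safe_div(0.32*(V+47.13), 1.0-std::exp(-0.1*(V+47.13)), 3.2);
  b = 0.08*std::exp(-V/11.0);
  dy[iM] = a*(1.0-y[iM]) - b*y[iM];
  // h, j
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0/(0.13*(1.0+std::exp(-(V+10.66)/11.1)));
    dy[iH] = a*(1.0-y[iH]) - b*y[iH];
    a = 0.0;
    b = 0.3*std::exp(-2.535e-7*V)/(1.0+std::exp(-0.1*(V+32.0)));
    dy[iJ] = a*(1.0-y[iJ]) - b*y[iJ];
  } else {
    a = 0.135*std::exp(-(V+80.0)/6.8);
    b = 3.56*std::exp(0.079*V) + 3.1e5*std::exp(0.35*V);
    dy[iH] = a*(1.0-y[iH]) - b*y[iH];
    a = (-127140.0*std::exp(0.2444*V) - 3.474e-5*std::exp(-0.04391*V)) *
        (V+37.78)/(1.0+std::exp(0.311*(V+79.23)));
    b = 0.1212*std::exp(-0.01052*V)/(1.0+std::exp(-0.1378*(V+40.14)));
    dy[iJ] = a*(1.0-y[iJ]) - b*y[iJ];
  }
  // oa, oi
  a = 0.65/(std::exp(-(V+10.0)/8.5) + std::exp(-(V-30.0)/59.0));
  b = 0.65/(2.5 + std::exp((V+82.0)/17.0));
  {
    double tau = 1.0/((a+b)*K_Q10);
    double inf = 1.0/(1.0+std::exp(-(V+20.47)/17.54));
    dy[iOA] = (inf - y[iOA])/tau;
  }
  a = 1.0/(18.53 + std::exp((V+113.7)/10.95));
  b = 1.0/(35.56 + std::exp(-(V+1.26)/7.44));
  {
    double tau = 1.0/((a+b)*K_Q10);
    double inf = 1.0/(1.0+std::exp((V+43.1)/5.3));
    dy[iOI] = (inf - y[iOI])/tau;
  }
  // ua, ui
  a = 0.65/(std::exp(-(V+10.0)/8.5) + std::exp(-(V-30.0)/59.0));
  b = 0.65/(2.5 + std::exp((V+82.0)/17.0));
  {
    double tau = 1.0/((a+b)*K_Q10);
    double inf = 1.0/(1.0+std::exp(-(V+30.3)/9.6));
    dy[iUA] = (inf - y[iUA])/tau;
  }
  a = 1.0/(21.0 + std::exp(-(V-185.0)/28.0));
  b = std::exp((V-158.0)/16.0);
  {
    double tau = 1.0/((a+b)*K_Q10);
    double inf = 1.0/(1.0+std::exp((V-99.45)/27.48));
    dy[iUI] = (inf - y[iUI])/tau;
  }
  // xr, xs
  a = safe_div(0.0003*(V+14.1), 1.0-std::exp(-(V+14.1)/5.0), 0.0015);
  b = safe_div(7.3898e-5*(V-3.3328), std::exp((V-3.3328)/5.1237)-1.0, 3.7864e-4);
  {
    double tau = 1.0/(a+b);
    double inf = 1.0/(1.0+std::exp(-(V+14.1)/6.5));
    dy[iXR] = (inf - y[iXR])/tau;
  }
  a = safe_div(4e-5*(V-19.9), 1.0-std::exp(-(V-19.9)/17.0), 6.8e-4);
  b = safe_div(3.5e-5*(V-19.9), std::exp((V-19.9)/9.0)-1.0, 3.15e-4);
  {
    double tau = 0.5/(a+b);
    double inf = std::pow(1.0+std::exp(-(V-19.9)/12.7), -0.5);
    dy[iXS] = (inf - y[iXS])/tau;
  }
  // d, f, fCa
  {
    double ex = std::exp(-(V+10.0)/6.24);
    double tau = safe_div(1.0-ex, 0.035*(V+10.0)*(1.0+ex), 2.28941);
    double inf = 1.0/(1.0+std::exp(-(V+10.0)/8.0));
    dy[iD] = (inf - y[iD])/tau;
  }
  {
    double inf = 1.0/(1.0+std::exp((V+28.0)/6.9));
    double tau = 9.0/(0.0197*std::exp(-0.0337*0.0337*(V+10.0)*(V+10.0)) + 0.02);
    dy[iF] = (inf - y[iF])/tau;
  }
  {
    double inf = 1.0/(1.0 + y[iCAI]/0.00035);
    dy[iFCA] = (inf - y[iFCA])/2.0;
  }
  // u, v, w
  {
    double eu = std::exp(-(Fn-3.4175e-13)/1.367e-15);
    double u_inf = 1.0/(1.0+eu);
    dy[iU] = (u_inf - y[iU])/8.0;
    double tau_v = 1.91 + 2.09/(1.0+eu);
    double v_inf = 1.0 - 1.0/(1.0+std::exp(-(Fn-6.835e-14)/1.367e-15));
    dy[iVG] = (v_inf - y[iVG])/tau_v;
  }
  {
    double ex = std::exp(-(V-7.9)/5.0);
    double tau = safe_div(6.0*(1.0-ex), (1.0+0.3*ex)*(V-7.9), 6.0*0.2/1.3);
    double inf = 1.0 - 1.0/(1.0+std::exp(-(V-40.0)/17.0));
    dy[iW] = (inf - y[iW])/tau;
  }

  // concentrations
  dy[iNAI] = Cm*(-3.0*i_NaK - (3.0*i_NaCa + i_B_Na + i_Na))/(V_i*Frdy);
  dy[iKI]  = Cm*(2.0*i_NaK - (i_K1+i_to+i_Kur+i_Kr+i_Ks+i_KACh))/(V_i*Frdy);
  {
    double B1 = Cm*(2.0*i_NaCa - (i_CaP + i_CaL + i_B_Ca))/(2.0*V_i*Frdy)
              + (V_up*(i_up_leak - i_up) + i_rel*V_rel)/V_i;
    double B2 = 1.0 + TRPN_max*Km_TRPN/std::pow(y[iCAI]+Km_TRPN,2)
              + CMDN_max*Km_CMDN/std::pow(y[iCAI]+Km_CMDN,2);
    dy[iCAI] = B1/B2;
  }
  dy[iCAUP]  = i_up - (i_up_leak + i_tr*V_rel/V_up);
  dy[iCAREL] = (i_tr - i_rel)/(1.0 + CSQN_max*Km_CSQN/std::pow(y[iCAREL]+Km_CSQN,2));

  const double i_ion = i_Na+i_K1+i_to+i_Kur+i_Kr+i_Ks+i_B_Na+i_B_Ca
                     + i_NaK+i_CaP+i_NaCa+i_CaL+i_KACh;
  if (iion_out) *iion_out = i_ion;
  dy[iV] = -i_ion + istim;
}

// exact MacCannell fibroblast RHS: y = (V, r, s)
static void fib_rhs(const double *y, double *dy, double istim, double *iion_out) {
  const double V = y[0], r = y[1], s = y[2];
  const double E_K  = RTF * std::log(K_o / FIB_KI);
  const double E_Na = RTF * std::log(Na_o / FIB_NAI);

  const double i_Kv = FIB_GKV * r * s * (V - E_K);
  const double vk = V - E_K;
  const double aK1 = 0.1/(1.0+std::exp(0.06*(vk-200.0)));
  const double bK1 = (3.0*std::exp(0.0002*(vk+100.0)) + std::exp(0.1*(vk-10.0))) /
                     (1.0+std::exp(-0.5*vk));
  const double i_K1 = FIB_GK1 * (aK1/(aK1+bK1)) * vk;
  const double i_NaK = FIB_INAK * (K_o/(K_o+FIB_KMK)) *
    (std::pow(FIB_NAI,1.5)/(std::pow(FIB_NAI,1.5)+std::pow(FIB_KMNA,1.5))) *
    (V - FIB_VREV)/(V - FIB_B);
  const double i_BNa = FIB_GBNA * (V - E_Na);

  const double r_inf = 1.0/(1.0+std::exp(-(V+20.0)/11.0));
  const double tau_r = 20.3 + 138.0*std::exp(-std::pow((V+20.0)/25.9,2));
  const double s_inf = 1.0/(1.0+std::exp((V+23.0)/7.0));
  const double tau_s = 1574.0 + 5268.0*std::exp(-std::pow((V+23.0)/22.7,2));

  dy[1] = (r_inf - r)/tau_r;
  dy[2] = (s_inf - s)/tau_s;
  const double i_ion = i_Kv + i_K1 + i_NaK + i_BNa;
  if (iion_out) *iion_out = i_ion;
  dy[0] = -i_ion + istim;
}

// [[Rcpp::export]]
NumericVector crn_rhs_cpp(NumericVector state, NumericVector scales,
                          double ach, double istim) {
  if (state.size() != NSTATE) stop("myocyte state must have 21 elements");
  for (int k = 0; k < NSTATE; ++k)
    if (!R_finite(state[k])) stop("non-finite state variable (numerical blow-up?)");
  double dach = ikach_dose_factor_cpp(ach);
  NumericVector dy(NSTATE);
  crn_rhs(REAL(state), REAL(dy), scales[0], scales[1], scales[2], scales[3],
          dach, istim, nullptr);
  return dy;
}

// [[Rcpp::export]]
NumericVector fib_rhs_cpp(NumericVector state, double istim) {
  if (state.size() != 3) stop("fibroblast state must have 3 elements (vm, r, s)");
  for (int k = 0; k < 3; ++k)
    if (!R_finite(state[k])) stop("non-finite state variable (numerical blow-up?)");
  NumericVector dy(3);
  fib_rhs(REAL(state), REAL(dy), istim, nullptr);
  return dy;
}

// ---------------------------------------------------------------------------
// Rate lookup table for the fast integrator
// ---------------------------------------------------------------------------
// For each tabulated V: per voltage gate, steady state and Rush-Larsen factors
// exp(-dt_lo/tau), exp(-dt_hi/tau); plus algebraic voltage-dependent factors.

static const double LUT_VMIN = -120.0;
static const double LUT_VMAX = 80.0;
static const double LUT_DV   = 0.05;
static const int    LUT_N    = (int)((LUT_VMAX - LUT_VMIN)/LUT_DV) + 1;

// myocyte voltage gates handled via LUT (RL): m h j oa oi ua ui xr xs d f w
static const int NGATE = 12;
// columns: NGATE*(inf, rl_lo, rl_hi) then algebraic:
// ik1v, gkurv, ikrv, fnak, e1, e2, kachv,
// fibroblast: rinf, r_lo, r_hi, sinf, s_lo, s_hi, fk1v, fnakv
static const int NALG = 7, NFIB = 8;
static const int LUT_NCOL = NGATE*3 + NALG + NFIB;

struct GateRate { double inf, tau; };

static GateRate gate_rate(int g, double V) {
  double a, b, inf, tau;
  switch (g) {
  case 0: // m
    a = safe_div(0.32*(V+47.13), 1.0-std::exp(-0.1*(V+47.13)), 3.2);
    b = 0.08*std::exp(-V/11.0);
    inf = a/(a+b); tau = 1.0/(a+b); break;
  case 1: // h
    if (V >= -40.0) { a = 0.0; b = 1.0/(0.13*(1.0+std::exp(-(V+10.66)/11.1))); }
    else { a = 0.135*std::exp(-(V+80.0)/6.8);
           b = 3.56*std::exp(0.079*V)+3.1e5*std::exp(0.35*V); }
    inf = a/(a+b); tau = 1.0/(a+b); break;
  case 2: // j
    if (V >= -40.0) { a = 0.0;
      b = 0.3*std::exp(-2.535e-7*V)/(1.0+std::exp(-0.1*(V+32.0))); }
    else {
      a = (-127140.0*std::exp(0.2444*V)-3.474e-5*std::exp(-0.04391*V))*
          (V+37.78)/(1.0+std::exp(0.311*(V+79.23)));
      b = 0.1212*std::exp(-0.01052*V)/(1.0+std::exp(-0.1378*(V+40.14)));
    }
    inf = a/(a+b); tau = 1.0/(a+b); break;
  case 3: // oa
    a = 0.65/(std::exp(-(V+10.0)/8.5)+std::exp(-(V-30.0)/59.0));
    b = 0.65/(2.5+std::exp((V+82.0)/17.0));
    tau = 1.0/((a+b)*K_Q10);
    inf = 1.0/(1.0+std::exp(-(V+20.47)/17.54)); break;
  case 4: // oi
    a = 1.0/(18.53+std::exp((V+113.7)/10.95));
    b = 1.0/(35.56+std::exp(-(V+1.26)/7.44));
    tau = 1.0/((a+b)*K_Q10);
    inf = 1.0/(1.0+std::exp((V+43.1)/5.3)); break;
  case 5: // ua
    a = 0.65/(std::exp(-(V+10.0)/8.5)+std::exp(-(V-30.0)/59.0));
    b = 0.65/(2.5+std::exp((V+82.0)/17.0));
    tau = 1.0/((a+b)*K_Q10);
    inf = 1.0/(1.0+std::exp(-(V+30.3)/9.6)); break;
  case 6: // ui
    a = 1.0/(21.0+std::exp(-(V-185.0)/28.0));
    b = std::exp((V-158.0)/16.0);
    tau = 1.0/((a+b)*K_Q10);
    inf = 1.0/(1.0+std::exp((V-99.45)/27.48)); break;
  case 7: // xr
    a = safe_div(0.0003*(V+14.1), 1.0-std::exp(-(V+14.1)/5.0), 0.0015);
    b = safe_div(7.3898e-5*(V-3.3328), std::exp((V-3.3328)/5.1237)-1.0, 3.7864e-4);
    tau = 1.0/(a+b);
    inf = 1.0/(1.0+std::exp(-(V+14.1)/6.5)); break;
  case 8: // xs
    a = safe_div(4e-5*(V-19.9), 1.0-std::exp(-(V-19.9)/17.0), 6.8e-4);
    b = safe_div(3.5e-5*(V-19.9), std::exp((V-19.9)/9.0)-1.0, 3.15e-4);
    tau = 0.5/(a+b);
    inf = std::pow(1.0+std::exp(-(V-19.9)/12.7), -0.5); break;
  case 9: { // d
    double ex = std::exp(-(V+10.0)/6.24);
    tau = safe_div(1.0-ex, 0.035*(V+10.0)*(1.0+ex), 2.28941);
    inf = 1.0/(1.0+std::exp(-(V+10.0)/8.0)); break; }
  case 10: // f
    inf = 1.0/(1.0+std::exp((V+28.0)/6.9));
    tau = 9.0/(0.0197*std::exp(-0.0337*0.0337*(V+10.0)*(V+10.0))+0.02); break;
  default: { // w
    double ex = std::exp(-(V-7.9)/5.0);
    tau = safe_div(6.0*(1.0-ex), (1.0+0.3*ex)*(V-7.9), 6.0*0.2/1.3);
    inf = 1.0 - 1.0/(1.0+std::exp(-(V-40.0)/17.0)); break; }
  }
  GateRate r; r.inf = inf; r.tau = tau; return r;
}

// [[Rcpp::export]]
NumericMatrix build_rate_lut_cpp(double dt_lo, double dt_hi) {
  NumericMatrix lut(LUT_N, LUT_NCOL);
  const double sigma = (std::exp(Na_o/67.3)-1.0)/7.0;
  for (int iv = 0; iv < LUT_N; ++iv) {
    double V = LUT_VMIN + iv*LUT_DV;
    int c = 0;
    for (int g = 0; g < NGATE; ++g) {
      GateRate r = gate_rate(g, V);
      lut(iv, c++) = r.inf;
      lut(iv, c++) = std::exp(-dt_lo/r.tau);
      lut(iv, c++) = std::exp(-dt_hi/r.tau);
    }
    lut(iv, c++) = 1.0/(1.0+std::exp(0.07*(V+80.0)));                    // ik1v
    lut(iv, c++) = 0.005+0.05/(1.0+std::exp(-(V-15.0)/13.0));            // gkurv
    lut(iv, c++) = 1.0/(1.0+std::exp((V+15.0)/22.4));                    // ikrv
    lut(iv, c++) = 1.0/(1.0+0.1245*std::exp(-0.1*V/RTF)
                        +0.0365*sigma*std::exp(-V/RTF));                 // fnak
    lut(iv, c++) = std::exp(gama*V/RTF);                                 // e1
    lut(iv, c++) = std::exp((gama-1.0)*V/RTF);                           // e2
    lut(iv, c++) = KACH_C1+KACH_C2/(1.0+std::exp((V+KACH_VH)/KACH_VS));  // kachv
    // fibroblast
    {
      double r_inf = 1.0/(1.0+std::exp(-(V+20.0)/11.0));
      double tau_r = 20.3+138.0*std::exp(-std::pow((V+20.0)/25.9,2));
      double s_inf = 1.0/(1.0+std::exp((V+23.0)/7.0));
      double tau_s = 1574.0+5268.0*std::exp(-std::pow((V+23.0)/22.7,2));
      lut(iv, c++) = r_inf;
      lut(iv, c++) = std::exp(-dt_lo/tau_r);
      lut(iv, c++) = std::exp(-dt_hi/tau_r);
      lut(iv, c++) = s_inf;
      lut(iv, c++) = std::exp(-dt_lo/tau_s);
      lut(iv, c++) = std::exp(-dt_hi/tau_s);
      double vk = V - RTF*std::log(K_o/FIB_KI);
      double aK1 = 0.1/(1.0+std::exp(0.06*(vk-200.0)));
      double bK1 = (3.0*std::exp(0.0002*(vk+100.0))+std::exp(0.1*(vk-10.0)))/
                   (1.0+std::exp(-0.5*vk));
      lut(iv, c++) = aK1/(aK1+bK1);                                      // fk1v
      lut(iv, c++) = (V-FIB_VREV)/(V-FIB_B);                             // fnakv
    }
  }
  return lut;
}

// fast per-node step context
struct NodeCache { double ENa, EK, ECa, naik; };  // naik = 1/(1+(KmNai/Nai)^1.5)

static inline void refresh_cache(const double *y, NodeCache &nc) {
  nc.ENa = RTF*std::log(Na_o/y[iNAI]);
  nc.EK  = RTF*std::log(K_o/y[iKI]);
  nc.ECa = 0.5*RTF*std::log(Ca_o/y[iCAI]);
  nc.naik = 1.0/(1.0+std::pow(Km_Na_i/y[iNAI],1.5));
}

// one myocyte step with the LUT; returns i_ion (pA/pF)
static inline double step_myocyte(double *y, const double *lutrow0,
                                  const double *lutrow1, double frac,
                                  double dt, int hi, const NodeCache &nc,
                                  double sgto, double sgcal, double sgkur,
                                  double sgk1, double dach,
                                  double exp_fca, double exp_u) {
#define LK(c) (lutrow0[c] + frac*(lutrow1[c]-lutrow0[c]))
  const double V = y[iV];
  const double E_Na = nc.ENa, E_K = nc.EK, E_Ca = nc.ECa;

  int c = NGATE*3;
  const double ik1v  = LK(c);     // c = 36
  const double gkurv = LK(c+1);
  const double ikrv  = LK(c+2);
  const double fnak  = LK(c+3);
  const double e1    = LK(c+4);
  const double e2    = LK(c+5);
  const double kachv = LK(c+6);

  static const double NAK_KFAC = K_o/(K_o+Km_K_o);
  static const double NACA_CDEN = 1.0 /
    ((K_mNa*K_mNa*K_mNa+Na_o*Na_o*Na_o)*(K_mCa+Ca_o));
  static const double INV_TAU_TR = 1.0/tau_tr;
  static const double INV_CAUPMAX = 1.0/Ca_up_max;

  const double cai = y[iCAI];
  // fold several small-denominator reciprocals into two divisions
  const double dA = 0.0005 + cai;            // IpCa
  const double dB = K_up + cai;              // Iup
  const double dC = 0.00035 + cai;           // fCa_inf
  const double dD = 1.0 + K_sat*e2;          // INaCa
  const double rAB = 1.0/(dA*dB), rCD = 1.0/(dC*dD);
  const double invA = rAB*dB, invB = rAB*dA, invC = rCD*dD, invD = rCD*dC;

  const double i_Na  = g_Na*y[iM]*y[iM]*y[iM]*y[iH]*y[iJ]*(V-E_Na);
  const double i_K1  = sgk1*g_K1*(V-E_K)*ik1v;
  const double i_to  = sgto*g_to*y[iOA]*y[iOA]*y[iOA]*y[iOI]*(V-E_K);
  const double i_Kur = sgkur*gkurv*y[iUA]*y[iUA]*y[iUA]*y[iUI]*(V-E_K);
  const double i_Kr  = g_Kr*y[iXR]*(V-E_K)*ikrv;
  const double i_Ks  = g_Ks*y[iXS]*y[iXS]*(V-E_K);
  const double i_CaL = sgcal*g_CaL*y[iD]*y[iF]*y[iFCA]*(V-65.0);
  const double i_CaP = i_CaP_max*cai*invA;
  const double i_NaK = i_NaK_max*fnak*nc.naik*NAK_KFAC;
  const double nai3  = y[iNAI]*y[iNAI]*y[iNAI];
  const double i_NaCa = I_NaCa_max*(e1*nai3*Ca_o - e2*Na_o*Na_o*Na_o*cai)*
    NACA_CDEN*invD;
  const double i_B_Na = g_B_Na*(V-E_Na);
  const double i_B_Ca = g_B_Ca*(V-E_Ca);
  const double i_KACh = dach*kachv*(V-E_K);

  const double i_rel = K_rel*y[iU]*y[iU]*y[iVG]*y[iW]*(y[iCAREL]-cai);
  const double i_tr  = (y[iCAUP]-y[iCAREL])*INV_TAU_TR;
  const double i_up  = I_up_max*cai*invB;
  const double i_up_leak = I_up_max*y[iCAUP]*INV_CAUPMAX;
  const double Fn = 1000.0*(1e-15*V_rel*i_rel
                    - (1e-15/(2.0*Frdy))*(0.5*i_CaL*Cm - 0.2*i_NaCa*Cm));

  // Rush-Larsen updates of the 12 voltage gates
  for (int g = 0; g < NGATE; ++g) {
    const int base = g*3;
    const int s = GATE_SLOT[g];
    const double inf = LK(base);
    const double rl  = hi ? LK(base+2) : LK(base+1);
    y[s] = inf + (y[s]-inf)*rl;
  }
  // fCa (constant tau 2 ms); fCa_inf = 0.00035/(0.00035+Cai)
  {
    const double inf = 0.00035*invC;
    y[iFCA] = inf + (y[iFCA]-inf)*exp_fca;
  }
  // u (constant tau 8 ms), v (Fn-dependent tau; forward Euler).
  // The logistic arguments saturate far from the release threshold; clamp to
  // skip the exponentials there (exact to double precision beyond |arg| 40).
  {
    const double au = -(Fn-3.4175e-13)/1.367e-15;
    double inv1;      // 1/(1+exp(au))
    if (au > 40.0) inv1 = 0.0;
    else if (au < -40.0) inv1 = 1.0;
    else inv1 = 1.0/(1.0+std::exp(au));
    const double u_inf = inv1;
    y[iU] = u_inf + (y[iU]-u_inf)*exp_u;
    const double tau_v = 1.91+2.09*inv1;
    const double av = -(Fn-6.835e-14)/1.367e-15;
    double inv2;
    if (av > 40.0) inv2 = 0.0;
    else if (av < -40.0) inv2 = 1.0;
    else inv2 = 1.0/(1.0+std::exp(av));
    const double v_inf = 1.0-inv2;
    y[iVG] += dt*(v_inf-y[iVG])/tau_v;
  }
  // concentrations (forward Euler)
  {
    static const double CMOVF = Cm/(V_i*Frdy);
    static const double INV_VI = 1.0/V_i;
    static const double VRELOVUP = V_rel/V_up;
    const double dNai = CMOVF*(-3.0*i_NaK-(3.0*i_NaCa+i_B_Na+i_Na));
    const double dKi  = CMOVF*(2.0*i_NaK-(i_K1+i_to+i_Kur+i_Kr+i_Ks+i_KACh));
    const double ct1 = cai+Km_TRPN, ct2 = cai+Km_CMDN;
    const double B1 = 0.5*CMOVF*(2.0*i_NaCa-(i_CaP+i_CaL+i_B_Ca))
                    + (V_up*(i_up_leak-i_up)+i_rel*V_rel)*INV_VI;
    const double cr = y[iCAREL]+Km_CSQN;
    const double q1 = ct1*ct1, q2 = ct2*ct2, q3 = cr*cr;
    const double B2q = q1*q2 + TRPN_max*Km_TRPN*q2 + CMDN_max*Km_CMDN*q1;
    const double rQ = 1.0/(B2q*(q3+CSQN_max*Km_CSQN));
    // 1/B2 = q1*q2/B2q ; 1/(1+csqn term) = q3/(q3+CSQN...)
    y[iNAI] += dt*dNai;
    y[iKI]  += dt*dKi;
    y[iCAI] += dt*B1*q1*q2*rQ*(q3+CSQN_max*Km_CSQN);
    y[iCAUP] += dt*(i_up-(i_up_leak+i_tr*VRELOVUP));
    y[iCAREL] += dt*(i_tr-i_rel)*q3*B2q*rQ;
  }
  return i_Na+i_K1+i_to+i_Kur+i_Kr+i_Ks+i_B_Na+i_B_Ca
        +i_NaK+i_CaP+i_NaCa+i_CaL+i_KACh;
#undef LK
}

static inline double step_fibroblast(double *y, const double *lutrow0,
                                     const double *lutrow1, double frac,
                                     int hi) {
#define LK(c) (lutrow0[c] + frac*(lutrow1[c]-lutrow0[c]))
  const double V = y[iV];
  const double E_K  = RTF*std::log(K_o/FIB_KI);   // constant; compiler folds
  const double E_Na = RTF*std::log(Na_o/FIB_NAI);
  int c = NGATE*3 + NALG;
  const double r_inf = LK(c);
  const double r_rl  = hi ? LK(c+2) : LK(c+1);
  const double s_inf = LK(c+3);
  const double s_rl  = hi ? LK(c+5) : LK(c+4);
  const double fk1v  = LK(c+6);
  const double fnakv = LK(c+7);

  const double i_Kv = FIB_GKV*y[iM]*y[iH]*(V-E_K);
  const double i_K1 = FIB_GK1*fk1v*(V-E_K);
  static const double napart =
    std::pow(FIB_NAI,1.5)/(std::pow(FIB_NAI,1.5)+std::pow(FIB_KMNA,1.5));
  const double i_NaK = FIB_INAK*(K_o/(K_o+FIB_KMK))*napart*fnakv;
  const double i_BNa = FIB_GBNA*(V-E_Na);

  y[iM] = r_inf + (y[iM]-r_inf)*r_rl;
  y[iH] = s_inf + (y[iH]-s_inf)*s_rl;
  return i_Kv+i_K1+i_NaK+i_BNa;
#undef LK
}

// ---------------------------------------------------------------------------
// Tissue / single-cell integrator
// ---------------------------------------------------------------------------
// label: 0 = myocyte, 1 = fibroblast. states: NSTATE x nnodes (column-major).
// Dx: edges parallel to x, length (nx-1)*ny; Dy: edges parallel to y, nx*(ny-1).
// Stimulus applied to stim_nodes (0-based) at each beat start for stim_dur ms.
// Recording: frames every sample_dt from t = record_from until t_total.

// [[Rcpp::export]]
List integrate_tissue_cpp(IntegerVector label, NumericMatrix states,
                          NumericVector sgto, NumericVector sgcal,
                          NumericVector sgkur, NumericVector sgk1,
                          NumericVector dach,
                          int nx, int ny, NumericVector Dx, NumericVector Dy,
                          double dx, IntegerVector stim_nodes,
                          double stim_amp, double stim_dur,
                          double cl, int n_beats, double t_total,
                          double dt_lo, double dt_hi, double dv_switch,
                          double record_from, double sample_dt) {
  const int N = nx*ny;
  if (label.size() != N) stop("label length != nx*ny");
  if (states.nrow() != NSTATE || states.ncol() != N)
    stop("states must be 21 x nnodes");
  if (dt_lo <= 0 || dt_hi < dt_lo) stop("invalid time-step range");

  NumericMatrix lut = build_rate_lut_cpp(dt_lo, dt_hi);
  // transpose to row-major for locality
  std::vector<double> lutr((size_t)LUT_N*LUT_NCOL);
  for (int iv = 0; iv < LUT_N; ++iv)
    for (int c2 = 0; c2 < LUT_NCOL; ++c2)
      lutr[(size_t)iv*LUT_NCOL+c2] = lut(iv, c2);

  std::vector<double> Y(REAL(states), REAL(states) + (size_t)NSTATE*N);
  std::vector<double> dvdiff(N, 0.0), Vb(N);
  std::vector<NodeCache> cache(N);
  std::vector<char> isfib(N);
  for (int n = 0; n < N; ++n) {
    isfib[n] = (char)(label[n] != 0);
    if (!isfib[n]) refresh_cache(&Y[(size_t)n*NSTATE], cache[n]);
  }
  std::vector<char> stim_mask(N, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int s = stim_nodes[k];
    if (s < 0 || s >= N) stop("stimulus node out of range");
    stim_mask[s] = 1;
  }

  const double exp_fca_lo = std::exp(-dt_lo/2.0), exp_fca_hi = std::exp(-dt_hi/2.0);
  const double exp_u_lo = std::exp(-dt_lo/8.0),   exp_u_hi = std::exp(-dt_hi/8.0);
  const double idx2 = 1.0/(dx*dx);

  const int nframes = (int)std::floor((t_total - record_from)/sample_dt) + 1;
  NumericMatrix vmout(nframes > 0 ? nframes : 0, N);
  int frame = 0;
  double next_rec = record_from;

  double t = 0.0;
  double maxdv_prev = 1e9;   // force small first step
  long nsteps = 0;
  double dt_sum = 0.0;
  const int cache_every = 10;
  int cache_ctr = 0;
  const bool adaptive = (dt_hi > dt_lo) ;

  while (t < t_total - 1e-9) {
    const int hi = (adaptive && maxdv_prev < dv_switch) ? 1 : 0;
    const double dt = hi ? dt_hi : dt_lo;
    const double exp_fca = hi ? exp_fca_hi : exp_fca_lo;
    const double exp_u   = hi ? exp_u_hi : exp_u_lo;

    // stimulus active?
    double stim_now = 0.0;
    if (stim_amp != 0.0 && n_beats > 0) {
      int beat = (int)std::floor(t/cl);
      double tb = t - beat*cl;
      if (beat < n_beats && tb < stim_dur) stim_now = stim_amp;
    }

    // diffusion pass (flux form, no-flux boundaries) on a contiguous V copy
    for (int n = 0; n < N; ++n) Vb[n] = Y[(size_t)n*NSTATE + iV];
    if (N > 1) {
      for (int i = 0; i < ny; ++i) {
        const double *drow = &Dx[(size_t)i*(nx-1)];
        for (int j = 0; j < nx; ++j) {
          const int n = i*nx + j;
          const double v = Vb[n];
          double acc = 0.0;
          if (j < nx-1) acc += drow[j] * (Vb[n+1]-v);
          if (j > 0)    acc += drow[j-1] * (Vb[n-1]-v);
          if (i < ny-1) acc += Dy[(size_t)i*nx+j] * (Vb[n+nx]-v);
          if (i > 0)    acc += Dy[(size_t)(i-1)*nx+j] * (Vb[n-nx]-v);
          dvdiff[n] = acc*idx2;
        }
      }
    }

    const bool do_cache = (cache_ctr == 0);
    double maxdv = 0.0;
    for (int n = 0; n < N; ++n) {
      double *y = &Y[(size_t)n*NSTATE];
      const double V = y[iV];
      if (!R_finite(V) || V < -120.0 || V > 80.0) {
        stop("membrane potential out of range (%.2f mV) at node %d, t = %.3f ms",
             V, n+1, t);
      }
      double pos = (V - LUT_VMIN)/LUT_DV;
      int ivx = (int)pos;
      if (ivx < 0) ivx = 0;
      if (ivx >= LUT_N-1) ivx = LUT_N-2;
      const double frac = pos - ivx;
      const double *row0 = &lutr[(size_t)ivx*LUT_NCOL];
      const double *row1 = row0 + LUT_NCOL;

      double iion;
      if (!isfib[n]) {
        if (do_cache) refresh_cache(y, cache[n]);
        iion = step_myocyte(y, row0, row1, frac, dt, hi, cache[n],
                            sgto[n], sgcal[n], sgkur[n], sgk1[n], dach[n],
                            exp_fca, exp_u);
      } else {
        iion = step_fibroblast(y, row0, row1, frac, hi);
      }
      // gap-junctional current divides by the node's own capacitance:
      // fibroblasts are ~16x smaller than myocytes, so the same edge
      // current moves their potential proportionally more
      const double cmul = isfib[n] ? (Cm / FIB_CM) : 1.0;
      double dvdt = -iion + cmul*dvdiff[n] + (stim_mask[n] ? stim_now : 0.0);
      y[iV] = V + dt*dvdt;
      double ad = std::fabs(dvdt);
      if (ad > maxdv) maxdv = ad;
    }
    maxdv_prev = maxdv;
    if (++cache_ctr >= cache_every) cache_ctr = 0;
    t += dt;
    ++nsteps;
    dt_sum += dt;

    if (frame < nframes && t >= next_rec - 1e-9) {
      for (int n = 0; n < N; ++n) vmout(frame, n) = Y[(size_t)n*NSTATE + iV];
      ++frame;
      next_rec = record_from + frame*sample_dt;
    }
    if ((nsteps & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(NSTATE, N);
  std::copy(Y.begin(), Y.end(), REAL(fin));
  NumericVector tvec(frame);
  for (int k = 0; k < frame; ++k) tvec[k] = record_from + k*sample_dt - (n_beats-1)*cl;

  return List::create(_["vm"] = vmout, _["t"] = tvec, _["frames"] = frame,
                      _["state"] = fin, _["nsteps"] = (double)nsteps,
                      _["dt_mean"] = dt_sum/nsteps);
}

// pure diffusion stepper (no ionic currents) for conservation tests
// [[Rcpp::export]]
NumericVector diffuse_cpp(NumericVector v0, int nx, int ny,
                          NumericVector Dx, NumericVector Dy,
                          double dx, double dt, int nsteps) {
  const int N = nx*ny;
  std::vector<double> v(REAL(v0), REAL(v0)+N), dvd(N);
  const double idx2 = 1.0/(dx*dx);
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < ny; ++i)
      for (int j = 0; j < nx; ++j) {
        const int n = i*nx+j;
        double acc = 0.0;
        if (j < nx-1) acc += Dx[(size_t)i*(nx-1)+j]*(v[n+1]-v[n]);
        if (j > 0)    acc += Dx[(size_t)i*(nx-1)+j-1]*(v[n-1]-v[n]);
        if (i < ny-1) acc += Dy[(size_t)i*nx+j]*(v[n+nx]-v[n]);
        if (i > 0)    acc += Dy[(size_t)(i-1)*nx+j]*(v[n-nx]-v[n]);
        dvd[n] = acc*idx2;
      }
    for (int n = 0; n < N; ++n) v[n] += dt*dvd[n];
  }
  NumericVector out(N);
  std::copy(v.begin(), v.end(), REAL(out));
  return out;
}
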
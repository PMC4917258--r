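// Core numerical engine for the NRAM ionic model and the 2D monolayer solver.
//
// State vector layout (per cell / per myocyte node), length NSTATE = 24:
//   0  V        membrane potential, mV
//   1..17       Hodgkin-Huxley gates: m h j d f fCa b g r s sslow ua ui Xr Xs1 Xs2 y
//   18 Catot_i  total cytosolic Ca (free + TRPN + CMDN bound), mM
//   19 Ca_NSR   free Ca in the network SR (unbuffered), mM
//   20 Catot_J  total junctional-SR Ca (free + CSQN bound), mM
//   21..23      RyR state occupancies R, O, I (RI = 1 - R - O - I)
//
// Free Ca is recovered from the conserved totals by inverting the rapid-buffer
// equilibria, so the closed Ca subsystem conserves total Ca exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

#define NSTATE 24
#define NGATE 17  // includes fCa (index 5 within gates, state index 6)

// gate order (state index 1..17)
// 0 m, 1 h, 2 j, 3 d, 4 f, 5 fCa, 6 b, 7 g, 8 r, 9 s, 10 sslow,
// 11 ua, 12 ui, 13 Xr, 14 Xs1, 15 Xs2, 16 y

struct Params {
  double T, Fc, RTF;
  double Nao, Nai, Ko, Ki, Cao;
  double ACh;
  double GNa, GCaL, GCaT, Gto, GKur, GKr, GKs, Gf, GNab, GCab;
  double kKsus, gK1scale, gK1pref, gKleak, gKAChc;
  double INaKmax, KmNai, KmKo, kNCX, etaNCX, dNCX;
  double ktauNa, ktauh, tauh0, Vth, Vhm, km, Vhh, kh, Vhy, ky, ktauXs;
  double Vup, Kmf, Kmr, Hup, tau_tr, kleak, ksrel;
  double koCa, kom, kiCa, kim, maxSR, minSR, ec50SR, hSR, KrelCa, nRyR;
  double TRPNtot, KmTRPN, CMDNtot, KmCMDN, CSQNtot, KmCSQN;
  double vNSR, vJSR;      // compartment volumes as fractions of cytosolic volume
  double kmem;            // (pA/pF) -> mM/ms conversion for membrane Ca flux
  double KfCa, tau_fCa, taug0, Vhb, Vhg, Vhd, Vhf;
  double Gfb, Efb, Ggap, Cfb;
  double block[12];       // INa ICaL ICaT Ito IKsus IK1 IKACh If INaK INCX INab ICab
};

static double getd(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("parameter '%s' missing", nm);
  return as<double>(p[nm]);
}

static Params as_params(const List& p) {
  Params P;
  P.T = getd(p, "T"); P.Fc = getd(p, "F");
  P.RTF = 8.314 * P.T / P.Fc;  // mV, with F in C/mmol
  P.Nao = getd(p, "Na_o"); P.Nai = getd(p, "Na_i");
  P.Ko = getd(p, "K_o");  P.Ki = getd(p, "K_i");  P.Cao = getd(p, "Ca_o");
  P.ACh = getd(p, "ACh");
  P.GNa = getd(p, "G_Na"); P.GCaL = getd(p, "G_CaL"); P.GCaT = getd(p, "G_CaT");
  P.Gto = getd(p, "G_to"); P.GKur = getd(p, "G_Kur"); P.GKr = getd(p, "G_Kr");
  P.GKs = getd(p, "G_Ks"); P.Gf = getd(p, "G_f");
  P.GNab = getd(p, "G_Nab"); P.GCab = getd(p, "G_Cab");
  P.kKsus = getd(p, "k_Ksus_scale"); P.gK1scale = getd(p, "gK1_scale");
  P.gK1pref = getd(p, "gK1_pref"); P.gKleak = getd(p, "g_Kleak");
  P.gKAChc = getd(p, "g_KACh_c");
  P.INaKmax = getd(p, "I_NaK_max"); P.KmNai = getd(p, "Km_Nai"); P.KmKo = getd(p, "Km_Ko");
  P.kNCX = getd(p, "k_NCX"); P.etaNCX = getd(p, "eta_NCX"); P.dNCX = getd(p, "d_NCX");
  P.ktauNa = getd(p, "k_tau_Na"); P.ktauh = getd(p, "k_tau_h");
  P.tauh0 = getd(p, "tau_h_min");
  P.Vhy = getd(p, "V_half_y"); P.ky = getd(p, "k_y");
  P.Vth = getd(p, "V_tau_h");
  P.ktauXs = getd(p, "k_tau_Xs");
  P.Vhm = getd(p, "V_half_m"); P.km = getd(p, "k_m");
  P.Vhh = getd(p, "V_half_h"); P.kh = getd(p, "k_h");
  P.Vup = getd(p, "V_max_up"); P.Kmf = getd(p, "Km_up_f"); P.Kmr = getd(p, "Km_up_r");
  P.Hup = getd(p, "H_up"); P.tau_tr = getd(p, "tau_tr");
  P.kleak = getd(p, "k_leak"); P.ksrel = getd(p, "k_s_rel");
  P.koCa = getd(p, "ko_Ca"); P.kom = getd(p, "ko_m");
  P.kiCa = getd(p, "ki_Ca"); P.kim = getd(p, "ki_m");
  P.maxSR = getd(p, "max_SR"); P.minSR = getd(p, "min_SR");
  P.ec50SR = getd(p, "EC50_SR"); P.hSR = getd(p, "h_SR");
  P.KrelCa = getd(p, "K_rel_Ca"); P.nRyR = getd(p, "n_RyR");
  P.TRPNtot = getd(p, "TRPN_tot"); P.KmTRPN = getd(p, "Km_TRPN");
  P.CMDNtot = getd(p, "CMDN_tot"); P.KmCMDN = getd(p, "Km_CMDN");
  P.CSQNtot = getd(p, "CSQN_tot"); P.KmCSQN = getd(p, "Km_CSQN");
  P.vNSR = getd(p, "v_NSR"); P.vJSR = getd(p, "v_JSR");
  double Cphys = getd(p, "C_cell_phys");  // pF
  double Vcyt = getd(p, "V_cyto_pL");     // pL
  // I [pA/pF] * Cphys [pF] = pA = 1e-15 C/ms; / (2 F Vcyto) -> mM/ms
  P.kmem = Cphys * 1e-15 / (2.0 * 96485.0 * Vcyt * 1e-12) * 1e3; // mol/m^3 == mM
  // (pA -> C/ms: 1e-15; Vcyto pL -> L: 1e-12; mol/L -> mM: 1e3)
  P.KfCa = getd(p, "K_fCa"); P.tau_fCa = getd(p, "tau_fCa");
  P.taug0 = getd(p, "tau_g_min");
  P.Vhb = getd(p, "V_half_b"); P.Vhg = getd(p, "V_half_g");
  P.Vhd = getd(p, "V_half_d"); P.Vhf = getd(p, "V_half_f");
  P.Gfb = getd(p, "G_fb"); P.Efb = getd(p, "E_fb");
  P.Ggap = getd(p, "G_gap"); P.Cfb = getd(p, "C_fb");
  NumericVector b = p["block"];
  if (b.size() != 12) stop("block vector must have length 12");
  for (int i = 0; i < 12; i++) P.block[i] = b[i];
  return P;
}

// ---- rapid-buffer inversions -------------------------------------------------

static double free_ca_cyt(double catot, const Params& P) {
  if (catot <= 0) return 0.0;
  // solve c + Tt c/(Kt+c) + Ct c/(Kc+c) = catot, Newton with safeguarded start
  double c = catot / (1.0 + P.TRPNtot / P.KmTRPN + P.CMDNtot / P.KmCMDN);
  if (c <= 0) c = 1e-9;
  for (int it = 0; it < 50; it++) {
    double bt = P.TRPNtot * c / (P.KmTRPN + c);
    double bc = P.CMDNtot * c / (P.KmCMDN + c);
    double f = c + bt + bc - catot;
    double df = 1.0 + P.TRPNtot * P.KmTRPN / ((P.KmTRPN + c) * (P.KmTRPN + c))
                    + P.CMDNtot * P.KmCMDN / ((P.KmCMDN + c) * (P.KmCMDN + c));
    double step = f / df;
    c -= step;
    if (c <= 0) c = 1e-12;
    if (std::fabs(step) < 1e-15 + 1e-12 * c) break;
  }
  return c;
}

static double free_ca_jsr(double catot, const Params& P) {
  if (catot <= 0) return 0.0;
  double b = P.KmCSQN + P.CSQNtot - catot;
  return 0.5 * (-b + std::sqrt(b * b + 4.0 * P.KmCSQN * catot));
}

// ---- gating kinetics ---------------------------------------------------------

// fills xinf[17], tau[17]; fCa entries (index 5) are placeholders (Ca-dependent)
static void gate_inf_tau(double V, const Params& P, double* xinf, double* tau) {
  // I_Na activation: steady state from neonatal atrial data, tau from Luo-Rudy
  // rates with a room-temperature slowdown factor k_tau_Na
  xinf[0] = 1.0 / (1.0 + std::exp(-(V - P.Vhm) / P.km));
  double dvm = V + 47.13;
  double am = (std::fabs(dvm) < 1e-6) ? 3.2 : 0.32 * dvm / (1.0 - std::exp(-0.1 * dvm));
  double bm = 0.08 * std::exp(-V / 11.0);
  tau[0] = P.ktauNa / (am + bm);
  // shared fast/slow inactivation steady state
  xinf[1] = 1.0 / (1.0 + std::exp((V - P.Vhh) / P.kh));
  tau[1] = P.ktauh * (P.tauh0 + 9.0 / (1.0 + std::exp((V - P.Vth) / 8.0)));
  xinf[2] = xinf[1];
  double aj, bj;
  if (V < -40.0) {
    aj = (-127140.0 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  tau[2] = P.ktauNa / (aj + bj);
  // I_CaL: d, f; tau_d carries the +10 ms correction
  xinf[3] = 1.0 / (1.0 + std::exp(-(V - P.Vhd) / 6.5));
  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  tau[3] = 10.0 + ad * bd + gd;
  xinf[4] = 1.0 / (1.0 + std::exp((V - P.Vhf) / 6.0));
  tau[4] = 1125.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
           165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  // fCa placeholder (Ca-dependent; computed in step)
  xinf[5] = 1.0; tau[5] = P.tau_fCa;
  // I_CaT: b, g
  xinf[6] = 1.0 / (1.0 + std::exp(-(V - P.Vhb) / 5.5));
  tau[6] = 1.0 + 5.0 / (1.0 + std::exp((V + 60.0) / 10.0));
  xinf[7] = 1.0 / (1.0 + std::exp((V - P.Vhg) / 5.5));
  tau[7] = P.taug0 + 32.0 / (1.0 + std::exp((V + 65.0) / 8.0));
  // I_to: r, s, sslow
  xinf[8] = 1.0 / (1.0 + std::exp(-(V + 10.6) / 11.42));
  tau[8] = 1000.0 / (45.16 * std::exp(0.03577 * (V + 50.0)) +
                     98.9 * std::exp(-0.1 * (V + 38.0)));
  xinf[9] = 1.0 / (1.0 + std::exp((V + 45.3) / 6.8841));
  tau[9] = 350.0 * std::exp(-((V + 70.0) / 15.0) * ((V + 70.0) / 15.0)) + 35.0;
  xinf[10] = xinf[9];
  tau[10] = 3700.0 * std::exp(-((V + 70.0) / 30.0) * ((V + 70.0) / 30.0)) + 35.0;
  // I_Kur: ua, ui
  xinf[11] = 1.0 / (1.0 + std::exp(-(V + 22.5) / 7.7));
  tau[11] = 0.493 * std::exp(-0.0629 * V) + 2.058;
  xinf[12] = 1.0 / (1.0 + std::exp((V + 45.2) / 5.7));
  tau[12] = 1200.0 - 170.0 / (1.0 + std::exp((V + 45.2) / 5.7));
  // I_Kr: Xr
  xinf[13] = 1.0 / (1.0 + std::exp(-(V + 15.0) / 6.0));
  tau[13] = 50.0 + 450.0 * std::exp(-(V + 30.0) * (V + 30.0) / 900.0);
  // I_Ks: Xs1, Xs2
  xinf[14] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 16.0));
  tau[14] = P.ktauXs * (200.0 + 800.0 * std::exp(-(V + 25.0) * (V + 25.0) / 1600.0));
  xinf[15] = xinf[14];
  tau[15] = 4.0 * tau[14];
  // I_f: y
  xinf[16] = 1.0 / (1.0 + std::exp((V - P.Vhy) / P.ky));
  tau[16] = 1000.0 / (0.11885 * std::exp((V + 75.0) / 28.37) +
                      0.56236 * std::exp(-(V + 75.0) / 14.19));
}

// [[Rcpp::export(name = ".cpp_gate_inf_tau")]]
NumericMatrix cpp_gate_inf_tau(NumericVector V, List params) {
  Params P = as_params(params);
  int n = V.size();
  NumericMatrix out(n, 2 * NGATE);
  double xinf[NGATE], tau[NGATE];
  for (int i = 0; i < n; i++) {
    gate_inf_tau(V[i], P, xinf, tau);
    for (int g = 0; g < NGATE; g++) { out(i, g) = xinf[g]; out(i, NGATE + g) = tau[g]; }
  }
  return out;
}

// ---- currents ----------------------------------------------------------------

// current indices in `cur`:
// 0 INa 1 ICaL 2 ICaT 3 Ito 4 IKur 5 IKr 6 IKs 7 IKsus 8 IK1 9 IKACh 10 If
// 11 INaK 12 INCX 13 INab 14 ICab 15 Itot 16 Jup 17 Jrel 18 Jleak 19 Jtr
#define NCUR 20

// mult: per-node multipliers (19) or NULL. order:
// GNa GCaL GCaT Gto GKur GKr GKs Gf GNab GCab gK1 gKleak gKACh INaK kNCX
// Vup ksrel kleak ktr
static void compute_currents(const double* s, const Params& P, int mode,
                             const double* mult, double* cur) {
  double one19[19];
  if (!mult) { for (int i = 0; i < 19; i++) one19[i] = 1.0; mult = one19; }
  double V = s[0];
  double Cai = free_ca_cyt(s[18], P);
  double CaNSR = s[19];
  double CaJSR = free_ca_jsr(s[20], P);
  double ENa = P.RTF * std::log(P.Nao / P.Nai);
  double EK  = P.RTF * std::log(P.Ko / P.Ki);
  double caimin = (Cai > 1e-8) ? Cai : 1e-8;
  double ECa = 0.5 * P.RTF * std::log(P.Cao / caimin);

  double INa = mult[0] * P.GNa * s[1]*s[1]*s[1] * s[2] * s[3] * (V - ENa);
  INa *= (1.0 - P.block[0]);

  double a = 2.0 * V / P.RTF;
  double ghk;
  if (std::fabs(a) < 1e-7) {
    ghk = 0.5 * P.Fc * (Cai - 0.341 * P.Cao);
  } else {
    ghk = (V * P.Fc / P.RTF) * (Cai * std::exp(a) - 0.341 * P.Cao) / std::expm1(a);
  }
  double ICaL = mult[1] * P.GCaL * 4.0 * s[4] * s[5] * s[6] * ghk;
  ICaL *= (1.0 - P.block[1]);

  double ICaT = mult[2] * P.GCaT * s[7] * s[8] * (V - ECa + 106.5);
  ICaT *= (1.0 - P.block[2]);

  double Ito = mult[3] * P.Gto * s[9] * (0.706 * s[10] + 0.294 * s[11]) * (V - EK);
  Ito *= (1.0 - P.block[3]);

  double IKur = mult[4] * P.GKur * s[12] * s[13] * (V - EK);
  double Rr = 1.0 / (1.0 + std::exp((V + 10.0) / 15.4));
  double IKr = mult[5] * P.GKr * s[14] * Rr * (V - EK);
  double IKs = mult[6] * P.GKs * s[15] * s[16] * (V - EK);
  double IKsus = P.kKsus * (IKur + IKr + IKs) * (1.0 - P.block[4]);

  double dk1 = V - EK - 10.0;
  double IK1 = mult[10] * P.gK1scale * P.gK1pref * (P.Ko / (P.Ko + 210.0)) *
               dk1 / (1.0 + std::exp(0.041 * dk1)) +
               mult[11] * P.gKleak * (V - EK);
  IK1 *= (1.0 - P.block[5]);

  double IKACh;
  double vfac = 1.0 / (1.0 + std::exp((V + 102.0) / 10.0));
  if (mode == 0) {
    double achp = (P.ACh > 0) ? std::pow(P.ACh, 0.477811) : 0.0;
    double dose = 3.5 * achp / (achp + 9.13652);
    IKACh = dose * (0.04 + 0.23 * vfac) * dk1;
  } else {
    IKACh = P.gKAChc * (0.075 + 0.35 * vfac) * dk1;
  }
  IKACh *= mult[12] * (1.0 - P.block[6]);

  double If = mult[7] * P.Gf * s[17] * (0.2 * (V - ENa) + 0.8 * (V - EK));
  If *= (1.0 - P.block[7]);

  double sig = (std::exp(P.Nao / 67.3) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / P.RTF) +
                       0.0365 * sig * std::exp(-V / P.RTF));
  double INaK = mult[13] * P.INaKmax * fNaK *
                (1.0 / (1.0 + std::pow(P.KmNai / P.Nai, 1.5))) *
                (P.Ko / (P.Ko + P.KmKo));
  INaK *= (1.0 - P.block[8]);

  double na3i = P.Nai * P.Nai * P.Nai, na3o = P.Nao * P.Nao * P.Nao;
  double INCX = mult[14] * P.kNCX *
      (na3i * P.Cao * std::exp(P.etaNCX * V / P.RTF) -
       na3o * Cai * std::exp((P.etaNCX - 1.0) * V / P.RTF)) /
      (1.0 + P.dNCX * (na3o * Cai + na3i * P.Cao));
  INCX *= (1.0 - P.block[9]);

  double INab = mult[8] * P.GNab * (V - ENa) * (1.0 - P.block[10]);
  double ICab = mult[9] * P.GCab * (V - ECa) * (1.0 - P.block[11]);

  // SR fluxes
  double fwd = std::pow(Cai / P.Kmf, P.Hup), rev = std::pow(CaNSR / P.Kmr, P.Hup);
  double Jup = mult[15] * P.Vup * (fwd - rev) / (1.0 + fwd + rev);
  double Jrel = mult[16] * P.ksrel * s[22] * (CaJSR - Cai);
  double Jleak = mult[17] * P.kleak * (CaNSR - Cai);
  double Jtr = mult[18] * (CaNSR - CaJSR) / P.tau_tr;

  cur[0] = INa; cur[1] = ICaL; cur[2] = ICaT; cur[3] = Ito;
  cur[4] = IKur; cur[5] = IKr; cur[6] = IKs; cur[7] = IKsus;
  cur[8] = IK1; cur[9] = IKACh; cur[10] = If; cur[11] = INaK; cur[12] = INCX;
  cur[13] = INab; cur[14] = ICab;
  cur[15] = INa + ICaL + IK1 + Ito + ICaT + ICab + INCX + INaK + If + INab +
            IKsus + IKACh;
  cur[16] = Jup; cur[17] = Jrel; cur[18] = Jleak; cur[19] = Jtr;
}

// [[Rcpp::export(name = ".cpp_currents")]]
NumericVector cpp_currents(NumericVector state, List params, int mode) {
  if (state.size() != NSTATE) stop("state must have length %d", NSTATE);
  Params P = as_params(params);
  double cur[NCUR];
  compute_currents(REAL(state), P, mode, nullptr, cur);
  NumericVector out(NCUR);
  for (int i = 0; i < NCUR; i++) out[i] = cur[i];
  out.attr("names") = CharacterVector::create(
    "I_Na","I_CaL","I_CaT","I_to","I_Kur","I_Kr","I_Ks","I_Ksus","I_K1",
    "I_KACh","I_f","I_NaK","I_NCX","I_Nab","I_Cab","I_total",
    "J_up","J_rel","J_leak","J_tr");
  return out;
}

// free Ca helper exposed for R-level bookkeeping
// [[Rcpp::export(name = ".cpp_free_ca")]]
NumericVector cpp_free_ca(NumericVector catot, List params, bool jsr) {
  Params P = as_params(params);
  int n = catot.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = jsr ? free_ca_jsr(catot[i], P) : free_ca_cyt(catot[i], P);
  return out;
}

// ---- voltage lookup tables ---------------------------------------------------

// voltage-dependent factors tabulated per time step (0.05 mV grid, linear
// interpolation); NVF slots per V entry hold the purely V-dependent parts of
// the current expressions so the stepper avoids per-node exponentials
#define NVF 9
// 0 ghkA = (VF/RTF) e^a / expm1(a)           (a = 2V/RTF)
// 1 ghkB = (VF/RTF) 0.341 Cao / expm1(a)
// 2 k1v  = gK1pref (Ko/(Ko+210)) dk1/(1+e^{0.041 dk1})
// 3 kach9  = dose9 (0.04 + 0.23 vfac) dk1    (single-cell form, params ACh)
// 4 kachc  = gKAChc (0.075 + 0.35 vfac) dk1  (constitutive form)
// 5 fnak   = NaK voltage factor
// 6 ncx1 = e^{eta V/RTF},  7 ncx2 = e^{(eta-1) V/RTF}
// 8 Rr   = 1/(1+e^{(V+10)/15.4})
struct VTab {
  double vmin, vmax, dv;
  int n;
  std::vector<double> xinf;  // n * NGATE
  std::vector<double> rlf;   // n * NGATE : 1 - exp(-dt/tau)
  std::vector<double> tau;   // n * NGATE
  std::vector<double> vf;    // n * NVF
  double EK, ENa;
  void build(const Params& P, double dt) {
    vmin = -200.0; vmax = 200.0; dv = 0.05;
    n = (int)((vmax - vmin) / dv) + 2;
    xinf.resize((size_t)n * NGATE); rlf.resize((size_t)n * NGATE);
    tau.resize((size_t)n * NGATE);
    vf.resize((size_t)n * NVF);
    EK = P.RTF * std::log(P.Ko / P.Ki);
    ENa = P.RTF * std::log(P.Nao / P.Nai);
    double xi[NGATE], tu[NGATE];
    double achp = (P.ACh > 0) ? std::pow(P.ACh, 0.477811) : 0.0;
    double dose9 = 3.5 * achp / (achp + 9.13652);
    double sig = (std::exp(P.Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < n; i++) {
      double V = vmin + i * dv;
      gate_inf_tau(V, P, xi, tu);
      for (int g = 0; g < NGATE; g++) {
        xinf[(size_t)i * NGATE + g] = xi[g];
        tau[(size_t)i * NGATE + g] = tu[g];
        rlf[(size_t)i * NGATE + g] = 1.0 - std::exp(-dt / tu[g]);
      }
      double* f = &vf[(size_t)i * NVF];
      double a = 2.0 * V / P.RTF;
      if (std::fabs(a) < 1e-7) {
        f[0] = 0.5 * P.Fc;
        f[1] = -0.5 * P.Fc * 0.341 * P.Cao;  // so Cai*ghkA + ghkB matches limit
      } else {
        double em = std::expm1(a);
        f[0] = (V * P.Fc / P.RTF) * std::exp(a) / em;
        f[1] = -(V * P.Fc / P.RTF) * 0.341 * P.Cao / em;
      }
      double dk1 = V - EK - 10.0;
      f[2] = P.gK1pref * (P.Ko / (P.Ko + 210.0)) * dk1 /
             (1.0 + std::exp(0.041 * dk1));
      double vfac = 1.0 / (1.0 + std::exp((V + 102.0) / 10.0));
      f[3] = dose9 * (0.04 + 0.23 * vfac) * dk1;
      f[4] = P.gKAChc * (0.075 + 0.35 * vfac) * dk1;
      f[5] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / P.RTF) +
                    0.0365 * sig * std::exp(-V / P.RTF));
      f[6] = std::exp(P.etaNCX * V / P.RTF);
      f[7] = std::exp((P.etaNCX - 1.0) * V / P.RTF);
      f[8] = 1.0 / (1.0 + std::exp((V + 10.0) / 15.4));
    }
  }
};

// fast tabulated current evaluation used inside the integrators; writes the
// same current set as compute_currents (interpolation error ~1e-6 relative)
static inline void currents_tab(const double* s, const Params& P,
                                const VTab& tab, int i0, double fr,
                                double Cai, double CaJSR, int mode,
                                const double* mult, double* cur) {
  double V = s[0];
  const double* f0 = &tab.vf[(size_t)i0 * NVF];
  const double* f1 = &tab.vf[(size_t)(i0 + 1) * NVF];
  double f[NVF];
  for (int k = 0; k < NVF; k++) f[k] = f0[k] + fr * (f1[k] - f0[k]);
  double EK = tab.EK, ENa = tab.ENa;
  double caimin = (Cai > 1e-8) ? Cai : 1e-8;
  double ECa = 0.5 * P.RTF * std::log(P.Cao / caimin);

  double INa = mult[0] * P.GNa * s[1]*s[1]*s[1] * s[2] * s[3] * (V - ENa) *
               (1.0 - P.block[0]);
  double ICaL = mult[1] * P.GCaL * 4.0 * s[4] * s[5] * s[6] *
                (Cai * f[0] + f[1]) * (1.0 - P.block[1]);
  double ICaT = mult[2] * P.GCaT * s[7] * s[8] * (V - ECa + 106.5) *
                (1.0 - P.block[2]);
  double Ito = mult[3] * P.Gto * s[9] * (0.706 * s[10] + 0.294 * s[11]) *
               (V - EK) * (1.0 - P.block[3]);
  double IKur = mult[4] * P.GKur * s[12] * s[13] * (V - EK);
  double IKr = mult[5] * P.GKr * s[14] * f[8] * (V - EK);
  double IKs = mult[6] * P.GKs * s[15] * s[16] * (V - EK);
  double IKsus = P.kKsus * (IKur + IKr + IKs) * (1.0 - P.block[4]);
  double IK1 = (mult[10] * P.gK1scale * f[2] +
                mult[11] * P.gKleak * (V - EK)) * (1.0 - P.block[5]);
  double IKACh = ((mode == 0) ? f[3] : f[4]) * mult[12] * (1.0 - P.block[6]);
  double If = mult[7] * P.Gf * s[17] * (0.2 * (V - ENa) + 0.8 * (V - EK)) *
              (1.0 - P.block[7]);
  double INaK = mult[13] * P.INaKmax * f[5] *
                (1.0 / (1.0 + std::pow(P.KmNai / P.Nai, 1.5))) *
                (P.Ko / (P.Ko + P.KmKo)) * (1.0 - P.block[8]);
  double na3i = P.Nai * P.Nai * P.Nai, na3o = P.Nao * P.Nao * P.Nao;
  double INCX = mult[14] * P.kNCX *
      (na3i * P.Cao * f[6] - na3o * Cai * f[7]) /
      (1.0 + P.dNCX * (na3o * Cai + na3i * P.Cao)) * (1.0 - P.block[9]);
  double INab = mult[8] * P.GNab * (V - ENa) * (1.0 - P.block[10]);
  double ICab = mult[9] * P.GCab * (V - ECa) * (1.0 - P.block[11]);

  double fwd = std::pow(Cai / P.Kmf, P.Hup), rev = std::pow(s[19] / P.Kmr, P.Hup);
  double Jup = mult[15] * P.Vup * (fwd - rev) / (1.0 + fwd + rev);
  double Jrel = mult[16] * P.ksrel * s[22] * (CaJSR - Cai);
  double Jleak = mult[17] * P.kleak * (s[19] - Cai);
  double Jtr = mult[18] * (s[19] - CaJSR) / P.tau_tr;

  cur[0] = INa; cur[1] = ICaL; cur[2] = ICaT; cur[3] = Ito;
  cur[4] = IKur; cur[5] = IKr; cur[6] = IKs; cur[7] = IKsus;
  cur[8] = IK1; cur[9] = IKACh; cur[10] = If; cur[11] = INaK; cur[12] = INCX;
  cur[13] = INab; cur[14] = ICab;
  cur[15] = INa + ICaL + IK1 + Ito + ICaT + ICab + INCX + INaK + If + INab +
            IKsus + IKACh;
  cur[16] = Jup; cur[17] = Jrel; cur[18] = Jleak; cur[19] = Jtr;
}

// ---- single-node step --------------------------------------------------------

struct StepWork { double cur[NCUR]; };

static void check_finite(const double* s, double t, int node);

static const double ones19[19] = {1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1};

static inline void step_node(double* s, const Params& P, const VTab& tab,
                             double dt, double istim, int mode,
                             const double* mult, bool euler_gates,
                             StepWork& w) {
  if (!mult) mult = ones19;
  double V = s[0];
  if (!(V > -1e6 && V < 1e6))   // catches NaN/Inf before table indexing
    check_finite(s, -1.0, -1);
  double Cai = free_ca_cyt(s[18], P);
  double CaJSR = free_ca_jsr(s[20], P);
  // table position (linear interpolation)
  double pos = (V - tab.vmin) / tab.dv;
  if (pos < 0) pos = 0;
  if (pos > tab.n - 2) pos = tab.n - 2;
  int i0 = (int)pos;
  double fr = pos - i0;
  currents_tab(s, P, tab, i0, fr, Cai, CaJSR, mode, mult, w.cur);
  const double* x0 = &tab.xinf[(size_t)i0 * NGATE];
  const double* x1 = &tab.xinf[(size_t)(i0 + 1) * NGATE];
  const double* r0 = &tab.rlf[(size_t)i0 * NGATE];
  const double* r1 = &tab.rlf[(size_t)(i0 + 1) * NGATE];
  const double* t0 = &tab.tau[(size_t)i0 * NGATE];
  const double* t1 = &tab.tau[(size_t)(i0 + 1) * NGATE];
  for (int g = 0; g < NGATE; g++) {
    double xi, rl, tu;
    if (g == 5) { // fCa, Ca-dependent
      double ratio = Cai / P.KfCa;
      xi = 1.0 / (1.0 + ratio * ratio);
      tu = P.tau_fCa;
      rl = tab.rlf[5];  // tau_fCa is V-independent: row 0 entry is exact
    } else {
      xi = x0[g] + fr * (x1[g] - x0[g]);
      rl = r0[g] + fr * (r1[g] - r0[g]);
      tu = t0[g] + fr * (t1[g] - t0[g]);
    }
    double x = s[1 + g];
    if (euler_gates) x += dt * (xi - x) / tu;
    else x += (xi - x) * rl;
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
    s[1 + g] = x;
  }
  // RyR (forward Euler)
  double kCaSR = P.maxSR - (P.maxSR - P.minSR) /
                 (1.0 + std::pow(P.ec50SR / ((CaJSR > 1e-6) ? CaJSR : 1e-6), P.hSR));
  double koSRCa = P.koCa / kCaSR;
  double kiSRCa = P.kiCa * kCaSR;
  // opening regulated by bulk cytosolic Ca through a steep Hill term
  // (adapted from the junctional-subspace formulation; see vignette)
  double trig = koSRCa * std::pow(Cai / P.KrelCa, P.nRyR);
  double R = s[21], O = s[22], I = s[23];
  double RI = 1.0 - R - O - I;
  double dR = (P.kim * RI - kiSRCa * Cai * R) - (trig * R - P.kom * O);
  double dO = (trig * R - P.kom * O) - (kiSRCa * Cai * O - P.kim * I);
  double dI = (kiSRCa * Cai * O - P.kim * I) - (P.kom * I - trig * RI);
  R += dt * dR; O += dt * dO; I += dt * dI;
  if (R < 0) R = 0; if (O < 0) O = 0; if (I < 0) I = 0;
  double sum = R + O + I;
  if (sum > 1.0) { R /= sum; O /= sum; I /= sum; }
  s[21] = R; s[22] = O; s[23] = I;
  // Ca compartments (totals; conservative by construction)
  double Jup = w.cur[16], Jrel = w.cur[17], Jleak = w.cur[18], Jtr = w.cur[19];
  double Jmem = -(w.cur[1] + w.cur[2] + w.cur[14] - 2.0 * w.cur[12]) * P.kmem;
  double rJC = P.vJSR, rNC = P.vNSR, rJN = P.vJSR / P.vNSR;
  s[18] += dt * (Jrel * rJC + Jleak - Jup + Jmem);
  s[19] += dt * ((Jup - Jleak) / rNC - Jtr * rJN);
  s[20] += dt * (Jtr - Jrel);
  if (s[18] < 0) s[18] = 0;
  if (s[19] < 0) s[19] = 0;
  if (s[20] < 0) s[20] = 0;
  // membrane potential (forward Euler; Cm = 1 uF/cm^2, pA/pF == uA/cm^2)
  s[0] = V + dt * (-(w.cur[15]) + istim);
}

static const char* state_names[NSTATE] = {
  "V","m","h","j","d","f","fCa","b","g","r","s","s_slow","ua","ui","Xr",
  "Xs1","Xs2","y","Ca_tot_i","Ca_NSR","Ca_tot_JSR","RyR_R","RyR_O","RyR_I"};

static void check_finite(const double* s, double t, int node) {
  for (int k = 0; k < NSTATE; k++) {
    if (!std::isfinite(s[k])) {
      if (node >= 0)
        stop("integration blow-up: state variable '%s' became non-finite at t = %.3f ms (node %d)",
             state_names[k], t, node + 1);
      if (t >= 0)
        stop("integration blow-up: state variable '%s' became non-finite at t = %.3f ms",
             state_names[k], t);
      stop("integration blow-up: state variable '%s' became non-finite",
           state_names[k]);
    }
  }
}

// ---- single-cell simulation --------------------------------------------------

// stim events: parallel vectors (start, duration, amplitude in pA/pF)
// [[Rcpp::export(name = ".cpp_simulate_cell")]]
List cpp_simulate_cell(NumericVector state0, List params, int mode,
                       double dt, double duration,
                       NumericVector stim_start, NumericVector stim_dur,
                       NumericVector stim_amp, double i_hold,
                       double record_dt, bool record_currents,
                       bool euler_gates) {
  if (state0.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (dt <= 0) stop("dt must be positive");
  Params P = as_params(params);
  VTab tab; tab.build(P, dt);
  double s[NSTATE];
  std::memcpy(s, REAL(state0), sizeof(s));
  long nstep = (long)std::llround(duration / dt);
  int every = (int)std::llround(record_dt / dt);
  if (every < 1) every = 1;
  long nrec = nstep / every + 1;
  NumericVector tout(nrec), Vout(nrec), Caout(nrec), NSRout(nrec), JSRout(nrec);
  NumericMatrix curout = record_currents ? NumericMatrix(nrec, NCUR)
                                         : NumericMatrix(1, 1);
  StepWork w;
  int ns = stim_start.size();
  long irec = 0;
  for (long step = 0; step <= nstep; step++) {
    double t = step * dt;
    if (step % every == 0 && irec < nrec) {
      tout[irec] = t; Vout[irec] = s[0];
      Caout[irec] = free_ca_cyt(s[18], P);
      NSRout[irec] = s[19];
      JSRout[irec] = free_ca_jsr(s[20], P);
      if (record_currents) {
        double cur[NCUR];
        compute_currents(s, P, mode, nullptr, cur);
        for (int k = 0; k < NCUR; k++) curout(irec, k) = cur[k];
      }
      irec++;
    }
    if (step == nstep) break;
    double istim = i_hold;
    for (int k = 0; k < ns; k++)
      if (t >= stim_start[k] && t < stim_start[k] + stim_dur[k]) istim += stim_amp[k];
    step_node(s, P, tab, dt, istim, mode, nullptr, euler_gates, w);
    if ((step & 0x3F) == 0) check_finite(s, t, -1);
  }
  check_finite(s, duration, -1);
  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; k++) fin[k] = s[k];
  fin.attr("names") = CharacterVector(state_names, state_names + NSTATE);
  List out = List::create(_["time"] = tout, _["V"] = Vout, _["Ca_i"] = Caout,
                          _["Ca_NSR"] = NSRout, _["Ca_JSR"] = JSRout,
                          _["final_state"] = fin);
  if (record_currents) out["currents"] = curout;
  return out;
}

// ---- tissue simulation -------------------------------------------------------

// grid encoding: type = 0 outside mask, 1 myocyte, 2 fibroblast (nx*ny, column-major)
// mult: matrix n_nodes x 19 (rows for all nodes; used only at myocyte nodes)
// stimulus events: list-free encoding via vectors + index list
// block events: step changes of the 12-entry block vector at given times
// [[Rcpp::export(name = ".cpp_simulate_tissue")]]
List cpp_simulate_tissue(NumericMatrix state0, NumericVector Vfb0,
                         IntegerVector type, int nx, int ny,
                         NumericMatrix mult, List params, int mode,
                         double dt, double duration, double D, double dx,
                         NumericVector stim_start, NumericVector stim_dur,
                         NumericVector stim_amp, List stim_nodes,
                         NumericVector block_time, IntegerVector block_idx,
                         NumericVector block_frac,
                         IntegerVector probe_nodes, double trace_dt,
                         double frame_dt, bool record_frames,
                         bool euler_gates, bool fb_coupled) {
  Params P = as_params(params);
  if (dt <= 0) stop("dt must be positive");
  double cfl = dx * dx / (4.0 * D);
  if (D > 0 && dt > cfl)
    stop("dt = %g ms violates the diffusion stability bound dx^2/(4D) = %g ms", dt, cfl);
  VTab tab; tab.build(P, dt);
  int nn = nx * ny;
  if (type.size() != nn) stop("type map size mismatch");
  // myocyte node list and index maps
  std::vector<int> myo, fib;
  std::vector<int> nodemap(nn, -1);
  for (int k = 0; k < nn; k++) {
    if (type[k] == 1) { nodemap[k] = (int)myo.size(); myo.push_back(k); }
    else if (type[k] == 2) { nodemap[k] = (int)fib.size(); fib.push_back(k); }
  }
  int nm = (int)myo.size(), nf = (int)fib.size();
  if (state0.nrow() != NSTATE || state0.ncol() != nm)
    stop("state0 must be %d x n_myocytes", NSTATE);
  if (Vfb0.size() != nf) stop("Vfb0 length mismatch");
  if (mult.nrow() != nn || mult.ncol() != 19) stop("mult must be n_nodes x 19");

  // neighbour lists (4-neighbour); Neumann no-flux at mask boundary:
  // only neighbours inside the mask contribute (V_nb - V) terms
  std::vector<int> nbr(4 * (size_t)nn, -1);
  for (int j = 0; j < ny; j++) for (int i = 0; i < nx; i++) {
    int k = i + nx * j;
    if (type[k] == 0) continue;
    int cand[4] = { (i > 0) ? k - 1 : -1, (i < nx - 1) ? k + 1 : -1,
                    (j > 0) ? k - nx : -1, (j < ny - 1) ? k + nx : -1 };
    for (int q = 0; q < 4; q++)
      nbr[4 * (size_t)k + q] = (cand[q] >= 0 && type[cand[q]] != 0) ? cand[q] : -1;
  }

  std::vector<double> S((size_t)NSTATE * nm);
  for (int c = 0; c < nm; c++)
    for (int r = 0; r < NSTATE; r++) S[(size_t)c * NSTATE + r] = state0(r, c);
  std::vector<double> Vfb(nf);
  for (int c = 0; c < nf; c++) Vfb[c] = Vfb0[c];
  std::vector<double> Vfield(nn, NA_REAL), Vnew(nn, NA_REAL);
  for (int c = 0; c < nm; c++) Vfield[myo[c]] = S[(size_t)c * NSTATE];
  for (int c = 0; c < nf; c++) Vfield[fib[c]] = Vfb[c];

  // stimulus amplitude per node, rebuilt when the active event set changes
  int ns = stim_start.size();
  std::vector<std::vector<int>> snodes(ns);
  for (int e = 0; e < ns; e++) {
    IntegerVector v = stim_nodes[e];
    snodes[e] = std::vector<int>(v.begin(), v.end()); // 0-based node indices
  }
  std::vector<double> stim_now(nn, 0.0);

  // block schedule
  int nb = block_time.size();
  std::vector<int> border(nb);
  for (int i = 0; i < nb; i++) border[i] = i;
  std::sort(border.begin(), border.end(),
            [&](int a, int b) { return block_time[a] < block_time[b]; });
  int bptr = 0;

  long nstep = (long)std::llround(duration / dt);
  int tevery = (int)std::llround(trace_dt / dt); if (tevery < 1) tevery = 1;
  int fevery = (int)std::llround(frame_dt / dt); if (fevery < 1) fevery = 1;
  long ntr = nstep / tevery + 1;
  long nfr = record_frames ? (nstep / fevery + 1) : 0;
  int np = probe_nodes.size();
  NumericMatrix traces(ntr, np);
  NumericVector ttimes(ntr);
  NumericVector frames(record_frames ? (R_xlen_t)nn * nfr : (R_xlen_t)1);
  NumericVector ftimes(record_frames ? nfr : 0);

  double D2 = D / (dx * dx);
  StepWork w;
  long itr = 0, ifr = 0;
  double t = 0.0;
  for (long step = 0; step <= nstep; step++) {
    t = step * dt;
    // recordings
    if (step % tevery == 0 && itr < ntr) {
      ttimes[itr] = t;
      for (int q = 0; q < np; q++) traces(itr, q) = Vfield[probe_nodes[q]];
      itr++;
    }
    if (record_frames && step % fevery == 0 && ifr < nfr) {
      ftimes[ifr] = t;
      std::memcpy(&frames[(R_xlen_t)nn * ifr], Vfield.data(), sizeof(double) * nn);
      ifr++;
    }
    if (step == nstep) break;
    // apply block events due
    while (bptr < nb && block_time[border[bptr]] <= t + 1e-9) {
      int e = border[bptr];
      P.block[block_idx[e]] = block_frac[e];
      bptr++;
    }
    // stimulus field for this step
    std::fill(stim_now.begin(), stim_now.end(), 0.0);
    for (int e = 0; e < ns; e++) {
      if (t >= stim_start[e] && t < stim_start[e] + stim_dur[e])
        for (int idx : snodes[e]) stim_now[idx] += stim_amp[e];
    }
    // advance myocytes
    for (int c = 0; c < nm; c++) {
      int k = myo[c];
      double* s = &S[(size_t)c * NSTATE];
      double V = Vfield[k];
      double diff = 0.0, gap = 0.0;
      for (int q = 0; q < 4; q++) {
        int kn = nbr[4 * (size_t)k + q];
        if (kn < 0) continue;
        if (type[kn] == 1) diff += (Vfield[kn] - V);
        else if (fb_coupled) gap += P.Ggap * (Vfield[kn] - V);
      }
      double istim = stim_now[k] + D2 * diff * 1.0 + gap; // D2*diff in mV/ms
      // step_node adds istim to dV/dt directly
      step_node(s, P, tab, dt, istim, mode, &mult(k, 0), euler_gates, w);
      Vnew[k] = s[0];
    }
    // advance fibroblasts (passive)
    for (int c = 0; c < nf; c++) {
      int k = fib[c];
      double V = Vfb[c];
      double gap = 0.0;
      if (fb_coupled) {
        for (int q = 0; q < 4; q++) {
          int kn = nbr[4 * (size_t)k + q];
          if (kn >= 0 && type[kn] == 1) gap += P.Ggap * (Vfield[kn] - V);
        }
      }
      double dV = -P.Gfb * (V - P.Efb) + gap;
      Vfb[c] = V + dt * dV;
      Vnew[k] = Vfb[c];
      if (!std::isfinite(Vfb[c]))
        stop("integration blow-up: fibroblast V non-finite at t = %.3f ms (node %d)", t, k + 1);
    }
    for (int c = 0; c < nm; c++) Vfield[myo[c]] = Vnew[myo[c]];
    for (int c = 0; c < nf; c++) Vfield[fib[c]] = Vnew[fib[c]];
    if ((step & 0xFF) == 0) {
      for (int c = 0; c < nm; c++)
        if (!std::isfinite(Vfield[myo[c]]))
          check_finite(&S[(size_t)c * NSTATE], t, myo[c]);
    }
  }
  for (int c = 0; c < nm; c++) check_finite(&S[(size_t)c * NSTATE], t, myo[c]);

  NumericMatrix Sout(NSTATE, nm);
  for (int c = 0; c < nm; c++)
    for (int r = 0; r < NSTATE; r++) Sout(r, c) = S[(size_t)c * NSTATE + r];
  NumericVector Vfbout(nf);
  for (int c = 0; c < nf; c++) Vfbout[c] = Vfb[c];
  List out = List::create(_["trace_time"] = ttimes, _["traces"] = traces,
                          _["final_state"] = Sout, _["V_fb"] = Vfbout,
                          _["myocyte_nodes"] = IntegerVector(myo.begin(), myo.end()),
                          _["fibroblast_nodes"] = IntegerVector(fib.begin(), fib.end()));
  if (record_frames) {
    frames.attr("dim") = IntegerVector::create(nx, ny, (int)nfr);
    out["frames"] = frames;
    out["frame_time"] = ftimes;
  }
  return out;
}
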
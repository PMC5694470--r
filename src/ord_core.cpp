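// O'Hara-Rudy 2011 human ventricular myocyte model (endo/mid/epi) with the
// Dutta et al. conductance-rescaled variant, drug conductance scaling, and a
// fixed-step forward-Euler integrator (optionally Rush-Larsen for gates).
//
// Voltage-dependent rate expressions are tabulated on a fine grid (0.01 mV,
// linear interpolation) so that the 0.001 ms fixed-step protocols required
// for EAD work run in seconds rather than minutes.  Reversal potentials and
// the IKs calcium-sensitivity factor are refreshed every 0.01 ms of
// simulated time; intracellular ion pools drift by < 1e-5 mM over that
// horizon so the approximation is far below solver error.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- fixed extracellular milieu and physical constants -------------------
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double vffrt_c = Frdy * Frdy / (Rgas * Temp);
static const double vfrt_c  = Frdy / (Rgas * Temp);

// cell geometry
static const double Lcell = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
static const double Ageo  = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
static const double Acap  = 2.0 * Ageo;
static const double vmyo  = 0.68 * vcell;
static const double vnsr  = 0.0552 * vcell;
static const double vjsr  = 0.0048 * vcell;
static const double vss   = 0.02 * vcell;

// CaMK
static const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
static const double CaMKo = 0.05, KmCaM = 0.0015;

// state indices
enum {
  iV = 0, iNai, iNass, iKi, iKss, iCai, iCass, iCansr, iCajsr,
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFF, iFS, iFcaf, iFcas, iJca, iNca, iFFp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1, iJrelnp, iJrelp, iCaMKt,
  NSTATE
};

static const int NGATE = 28; // gates integrated as dg/dt = (ss - g)/tau
// gate -> state index
static const int gate_state[NGATE] = {
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFF, iFS, iFcaf, iFcas, iJca, iFFp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1
};

// ---- lookup tables -------------------------------------------------------
// per node: [0..27] gate ss, [28..55] gate 1/tau, then extras
enum {
  Q_SS0 = 0, Q_ITAU0 = NGATE,
  Q_EXPV = 2 * NGATE, Q_EXP2V, Q_A1, Q_A2, Q_HCA, Q_HNA,
  Q_FKNAI, Q_FKNAO, Q_XKB, Q_RKR, Q_RK1, Q_AIF, Q_AFCAF, Q_AXRF,
  Q_IDELTAEPI,
  NQ
};

static const double VMIN = -150.0, VMAX = 100.0, DV = 0.01;
static const int NV = (int)((VMAX - VMIN) / DV) + 1;
static std::vector<double> TAB;      // NV * NQ, node-major
static std::vector<double> RLTAB;    // NV * NGATE: exp(-dt/tau), for RL mode
static double RLTAB_dt = -1.0;

// fill gate ss/tau and extras at voltage v into q[NQ]
static void table_row(double v, double *q) {
  // INa
  double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
  double tm  = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                      8.552 * exp(-(v + 77.42) / 5.955));
  double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
  double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                      6.149 * exp((v + 0.5096) / 20.27));
  double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                      0.3343 * exp((v + 5.730) / 56.66));
  double jss = hss;
  double tj  = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                              0.3052 * exp((v + 0.9941) / 38.45));
  double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
  double thsp = 3.0 * ths;
  double tjp  = 1.46 * tj;
  // INaL
  double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
  double tmL  = tm;
  double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
  double thL  = 200.0;
  double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
  double thLp  = 3.0 * thL;
  // Ito
  double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
  double ta  = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                         3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
  double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
  double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                              0.08004 * exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * exp((v + 114.1) / 8.079));
  double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
  double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                         exp(-(v - 12.23) / 0.2154));
  double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
  double tiFp = dti_develop * dti_recover * tiF;
  double tiSp = dti_develop * dti_recover * tiS;
  // ICaL
  double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
  double td  = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
  double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
  double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                            0.0045 * exp((v + 20.0) / 10.0));
  double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                               0.000035 * exp((v + 5.0) / 6.0));
  double fcass = fss;
  double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                              0.04 * exp((v - 4.0) / 7.0));
  double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                0.00012 * exp(v / 7.0));
  double tjca = 75.0;
  double tffp = 2.5 * tff;
  double tfcafp = 2.5 * tfcaf;
  // IKr
  double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
  double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                               4.123e-5 * exp(-(v - 47.78) / 20.38));
  double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                               1.128e-5 * exp(-(v - 29.74) / 25.94));
  // IKs
  double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
  double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                               0.001292 * exp(-(v + 210.0) / 230.0));
  double xs2ss = xs1ss;
  double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                       0.0193 * exp(-(v + 66.54) / 31.0));
  // IK1
  double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                  (1.5692 * ko + 3.8115)));
  double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33));

  double ss[NGATE] = {
    mss, hss, hss, jss, hssp, jss, mLss, hLss, hLssp,
    ass, iss, iss, assp, iss, iss,
    dss, fss, fss, fcass, fcass, fcass, fss, fcass,
    xrss, xrss, xs1ss, xs2ss, xk1ss
  };
  double tau[NGATE] = {
    tm, thf, ths, tj, thsp, tjp, tmL, thL, thLp,
    ta, tiF, tiS, ta, tiFp, tiSp,
    td, tff, tfs, tfcaf, tfcas, tjca, tffp, tfcafp,
    txrf, txrs, txs1, txs2, txk1
  };
  for (int g = 0; g < NGATE; g++) {
    q[Q_SS0 + g] = ss[g];
    q[Q_ITAU0 + g] = 1.0 / tau[g];
  }

  double x = v * vfrt_c;
  double ex = exp(x), e2x = exp(2.0 * x);
  q[Q_EXPV]  = ex;
  q[Q_EXP2V] = e2x;
  if (fabs(v) < 1e-7) {
    q[Q_A1] = Frdy;        // lim v->0 of vffrt/(e^x - 1)
    q[Q_A2] = 2.0 * Frdy;  // lim v->0 of 4 vffrt/(e^2x - 1)
  } else {
    double vffrt = v * vffrt_c;
    q[Q_A1] = vffrt / (ex - 1.0);
    q[Q_A2] = 4.0 * vffrt / (e2x - 1.0);
  }
  q[Q_HCA] = exp(0.1670 * x);
  q[Q_HNA] = exp(0.5224 * x);
  // stored as reciprocal Michaelis constants 1/Knai(v), 1/Knao(v)
  q[Q_FKNAI] = 1.0 / (9.073 * exp(-0.1550 * x / 3.0));
  q[Q_FKNAO] = 1.0 / (27.78 * exp((1.0 + 0.1550) * x / 3.0));
  q[Q_XKB] = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
  q[Q_RKR] = 1.0 / (1.0 + exp((v + 55.0) / 75.0)) *
             1.0 / (1.0 + exp((v - 10.0) / 30.0));
  q[Q_RK1] = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
  q[Q_AIF] = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
  q[Q_AFCAF] = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
  q[Q_AXRF] = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
  // epi-only slowing factor of Ito inactivation, stored as its inverse
  double delta_epi = 1.0 - 0.95 / (1.0 + exp((v + 70.0) / 5.0));
  q[Q_IDELTAEPI] = 1.0 / delta_epi;
}

static void build_tables() {
  if (!TAB.empty()) return;
  TAB.resize((size_t)NV * NQ);
  for (int i = 0; i < NV; i++) table_row(VMIN + i * DV, &TAB[(size_t)i * NQ]);
}

static void build_rl_tables(double dt) {
  if (RLTAB_dt == dt && !RLTAB.empty()) return;
  build_tables();
  RLTAB.resize((size_t)NV * NGATE);
  for (int i = 0; i < NV; i++)
    for (int g = 0; g < NGATE; g++)
      RLTAB[(size_t)i * NGATE + g] =
        exp(-dt * TAB[(size_t)i * NQ + Q_ITAU0 + g]);
  RLTAB_dt = dt;
}

// ---- scaled model parameters --------------------------------------------
struct Pars {
  double GNa, GNaL, Gto, PCa, GKr, GKs, GK1, Gncx, Pnak, GKb;
  double PNab, PCab, GpCa;
  double cmdnmax, jup_f, jrel_f;
  int celltype; // 0 endo, 1 epi, 2 mid
};

static Pars make_pars(int celltype, int variant, double gnal_scale,
                      const double *mult) {
  Pars p;
  p.celltype = celltype;
  p.GNa = 75.0; p.GNaL = 0.0075; p.Gto = 0.02; p.PCa = 0.0001;
  p.GKr = 0.046; p.GKs = 0.0034; p.GK1 = 0.1908;
  p.Gncx = 0.0008; p.Pnak = 30.0; p.GKb = 0.003;
  p.PNab = 3.75e-10; p.PCab = 2.5e-8; p.GpCa = 0.0005;
  p.cmdnmax = 0.05; p.jup_f = 1.0; p.jrel_f = 1.0;
  if (celltype == 1) { // epi
    p.GNaL *= 0.6; p.Gto *= 4.0; p.PCa *= 1.2; p.GKr *= 1.3; p.GKs *= 1.4;
    p.GK1 *= 1.2; p.Gncx *= 1.1; p.Pnak *= 0.9; p.GKb *= 0.6;
    p.cmdnmax *= 1.3; p.jup_f = 1.3;
  } else if (celltype == 2) { // mid
    p.Gto *= 4.0; p.PCa *= 2.5; p.GKr *= 0.8; p.GK1 *= 1.3;
    p.Gncx *= 1.4; p.Pnak *= 0.7; p.jrel_f = 1.7;
  }
  if (variant == 1) { // Dutta et al. rescaling of the ORd baseline
    p.GKr *= 1.013; p.GKs *= 1.870; p.GK1 *= 1.698;
    p.GNaL *= 2.661; p.PCa *= 1.007;
  }
  p.GNaL *= gnal_scale; // LQT3-style late-sodium enhancement
  // drug block multipliers: IKr, ICaV, INaL, INa_fast, IKs, IK1, Ito
  p.GKr *= mult[0]; p.PCa *= mult[1]; p.GNaL *= mult[2]; p.GNa *= mult[3];
  p.GKs *= mult[4]; p.GK1 *= mult[5]; p.Gto *= mult[6];
  return p;
}

// [[Rcpp::export]]
NumericVector ord_initial_state_cpp() {
  NumericVector s(NSTATE);
  s[iV] = -87.0; s[iNai] = 7.0; s[iNass] = 7.0; s[iKi] = 145.0; s[iKss] = 145.0;
  s[iCai] = 1.0e-4; s[iCass] = 1.0e-4; s[iCansr] = 1.2; s[iCajsr] = 1.2;
  s[iM] = 0; s[iHf] = 1; s[iHs] = 1; s[iJ] = 1; s[iHsp] = 1; s[iJp] = 1;
  s[iML] = 0; s[iHL] = 1; s[iHLp] = 1;
  s[iA] = 0; s[iIF] = 1; s[iIS] = 1; s[iAp] = 0; s[iIFp] = 1; s[iISp] = 1;
  s[iD] = 0; s[iFF] = 1; s[iFS] = 1; s[iFcaf] = 1; s[iFcas] = 1; s[iJca] = 1;
  s[iNca] = 0; s[iFFp] = 1; s[iFcafp] = 1;
  s[iXrf] = 0; s[iXrs] = 0; s[iXs1] = 0; s[iXs2] = 0; s[iXk1] = 1;
  s[iJrelnp] = 0; s[iJrelp] = 0; s[iCaMKt] = 0;
  CharacterVector nm = CharacterVector::create(
    "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt");
  s.attr("names") = nm;
  return s;
}

// [[Rcpp::export]]
List ord_run_cpp(NumericVector state0, int celltype, int variant,
                 double gnal_scale, NumericVector mult,
                 double t0, double t_end, NumericVector stim_times,
                 double stim_amp, double stim_dur, double dt,
                 double record_start, double record_dt, int method) {
  build_tables();
  if (method == 1) build_rl_tables(dt);
  if (state0.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  if (mult.size() != 7) stop("mult must have 7 entries");
  Pars P = make_pars(celltype, variant, gnal_scale, REAL(mult));

  double s[NSTATE];
  for (int i = 0; i < NSTATE; i++) s[i] = state0[i];

  long long nstep = (long long)llround((t_end - t0) / dt);
  long long rec_from = (long long)llround((record_start - t0) / dt);
  long long rec_every = (long long)llround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  long long cache_every = (long long)llround(0.01 / dt);
  if (cache_every < 1) cache_every = 1;
  long long dur_steps = (long long)llround(stim_dur / dt);

  std::vector<double> rt, rv, rca, rjsr;
  if (rec_from <= nstep) {
    size_t cap = (size_t)((nstep - std::max(rec_from, 0LL)) / rec_every + 2);
    rt.reserve(cap); rv.reserve(cap); rca.reserve(cap);
  }

  // stimulus step schedule
  int nstim = stim_times.size();
  std::vector<long long> stim_start(nstim);
  for (int i = 0; i < nstim; i++)
    stim_start[i] = (long long)llround((stim_times[i] - t0) / dt);
  int stim_idx = 0;

  double ENa = 0, EK = 0, EKs = 0, KsCa = 1;
  bool blowup = false; double blowup_t = NA_REAL;

  const double *tb = &TAB[0];

  for (long long step = 0; step <= nstep; step++) {
    double v = s[iV];
    if (!std::isfinite(v) || fabs(v) > 500.0) {
      blowup = true; blowup_t = t0 + step * dt; break;
    }

    if (step % cache_every == 0) {
      ENa = (Rgas * Temp / Frdy) * log(nao / s[iNai]);
      EK  = (Rgas * Temp / Frdy) * log(ko / s[iKi]);
      EKs = (Rgas * Temp / Frdy) *
            log((ko + 0.01833 * nao) / (s[iKi] + 0.01833 * s[iNai]));
      KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / s[iCai], 1.4));
    }

    // table lookup
    double u = (v - VMIN) / DV;
    if (u < 0) u = 0;
    if (u > NV - 1.001) u = NV - 1.001;
    int ix = (int)u;
    double w = u - ix;
    const double *p0 = tb + (size_t)ix * NQ;
    const double *p1 = p0 + NQ;
#define LK(qq) (p0[qq] + w * (p1[qq] - p0[qq]))

    if (step >= rec_from && (step - rec_from) % rec_every == 0) {
      rt.push_back(t0 + step * dt);
      rv.push_back(v);
      rca.push_back(s[iCai]);
      rjsr.push_back(s[iCajsr]);
    }
    if (step == nstep) break;

    // stimulus
    double Ist = 0.0;
    while (stim_idx < nstim && step >= stim_start[stim_idx] + dur_steps)
      stim_idx++;
    if (stim_idx < nstim && step >= stim_start[stim_idx] &&
        step < stim_start[stim_idx] + dur_steps)
      Ist = stim_amp;

    double nai = s[iNai], nass = s[iNass], ki = s[iKi], kss = s[iKss];
    double cai = s[iCai], cass = s[iCass], cansr = s[iCansr], cajsr = s[iCajsr];

    // CaMK
    double CaMKb = CaMKo * (1.0 - s[iCaMKt]) * cass / (cass + KmCaM);
    double CaMKa = CaMKb + s[iCaMKt];
    double fp = CaMKa / (CaMKa + KmCaMK); // phosphorylated fraction

    // INa
    double h  = 0.99 * s[iHf] + 0.01 * s[iHs];
    double hp = 0.99 * s[iHf] + 0.01 * s[iHsp];
    double m3 = s[iM] * s[iM] * s[iM];
    double INa = P.GNa * (v - ENa) * m3 *
                 ((1.0 - fp) * h * s[iJ] + fp * hp * s[iJp]);
    // INaL
    double INaL = P.GNaL * (v - ENa) * s[iML] *
                  ((1.0 - fp) * s[iHL] + fp * s[iHLp]);
    // Ito
    double AiF = LK(Q_AIF), AiS = 1.0 - AiF;
    double ito_i  = AiF * s[iIF] + AiS * s[iIS];
    double ito_ip = AiF * s[iIFp] + AiS * s[iISp];
    double Ito = P.Gto * (v - EK) *
                 ((1.0 - fp) * s[iA] * ito_i + fp * s[iAp] * ito_ip);
    // ICaL / ICaNa / ICaK
    double expv = LK(Q_EXPV), exp2v = LK(Q_EXP2V);
    double A1 = LK(Q_A1), A2 = LK(Q_A2);
    double PhiCaL  = A2 * (cass * exp2v - 0.341 * cao);
    double PhiCaNa = A1 * (0.75 * nass * expv - 0.75 * nao);
    double PhiCaK  = A1 * (0.75 * kss * expv - 0.75 * ko);
    double PCa = P.PCa, PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double Afcaf = LK(Q_AFCAF), Afcas = 1.0 - Afcaf;
    double f   = 0.6 * s[iFF] + 0.4 * s[iFS];
    double fca = Afcaf * s[iFcaf] + Afcas * s[iFcas];
    double fpp  = 0.6 * s[iFFp] + 0.4 * s[iFS];
    double fcap = Afcaf * s[iFcafp] + Afcas * s[iFcas];
    double nca = s[iNca], jca = s[iJca], d = s[iD];
    double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
    double gate_p  = d * (fpp * (1.0 - nca) + jca * fcap * nca);
    double ICaL  = (1.0 - fp) * PCa  * PhiCaL  * gate_np +
                   fp * PCap  * PhiCaL  * gate_p;
    double ICaNa = (1.0 - fp) * PCaNa * PhiCaNa * gate_np +
                   fp * PCaNap * PhiCaNa * gate_p;
    double ICaK  = (1.0 - fp) * PCaK * PhiCaK * gate_np +
                   fp * PCaKp * PhiCaK * gate_p;
    // IKr
    double Axrf = LK(Q_AXRF);
    double xr = Axrf * s[iXrf] + (1.0 - Axrf) * s[iXrs];
    double IKr = P.GKr * xr * LK(Q_RKR) * (v - EK); // sqrt(ko/5.4) = 1
    // IKs
    double IKs = P.GKs * KsCa * s[iXs1] * s[iXs2] * (v - EKs);
    // IK1
    static const double sqko = 2.3237900077244501;  // sqrt(5.4)
    double IK1 = P.GK1 * sqko * LK(Q_RK1) * s[iXk1] * (v - EK);
    // INaCa (myoplasmic and subspace components)
    double hca = LK(Q_HCA), hna = LK(Q_HNA);
    double INaCa_i = 0.0, INaCa_ss = 0.0;
    {
      const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
      const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
      const double kcaon = 1.5e6, kcaoff = 5.0e3, KmCaAct = 150.0e-6;
      const double ikna1 = 1.0 / kna1, ikna2 = 1.0 / kna2, ikna3 = 1.0 / kna3;
      double inv_hna = 1.0 / hna, inv_hca = 1.0 / hca;
      double h7 = 1.0 + nao * ikna3 * (1.0 + inv_hna);
      double inv_h7 = 1.0 / h7;
      double h8 = nao * ikna3 * inv_hna * inv_h7;
      double h9 = inv_h7;
      double h10 = kasymm + 1.0 + nao * ikna1 * (1.0 + nao * ikna2);
      double inv_h10 = 1.0 / h10;
      double h11 = nao * nao * inv_h10 * ikna1 * ikna2;
      double h12 = inv_h10;
      double k1 = h12 * cao * kcaon, k2 = kcaoff, k5 = kcaoff;
      for (int comp = 0; comp < 2; comp++) {
        double na = comp ? nass : nai;
        double ca = comp ? cass : cai;
        double h1 = 1.0 + na * ikna3 * (1.0 + hna);
        double inv_h1 = 1.0 / h1;
        double h2 = na * hna * ikna3 * inv_h1;
        double h3 = inv_h1;
        double h4 = 1.0 + na * ikna1 * (1.0 + na * ikna2);
        double inv_h4 = 1.0 / h4;
        double h5 = na * na * inv_h4 * ikna1 * ikna2;
        double h6 = inv_h4;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca * inv_hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k6 = h6 * ca * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double sxinv = 1.0 / (x1 + x2 + x3 + x4);
        double E1 = x1 * sxinv, E2 = x2 * sxinv, E3 = x3 * sxinv,
               E4 = x4 * sxinv;
        double r = KmCaAct / ca;
        double allo = 1.0 / (1.0 + r * r);
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        double val = P.Gncx * allo * (JncxNa + 2.0 * JncxCa);
        if (comp) INaCa_ss = 0.2 * val; else INaCa_i = 0.8 * val;
      }
    }
    // INaK
    double INaK, JnakNa, JnakK;
    {
      const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
      const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
      const double Kki = 0.5, Kko = 0.3582;
      const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
      const double Hp = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
      const double Knap = 224.0, Kxkur = 292.0;
      double rni = nai * LK(Q_FKNAI), rki = ki / Kki;
      double rno = nao * LK(Q_FKNAO), rko = ko / Kko;
      double Pfrac = eP / (1.0 + Hp / Khp + nai / Knap + ki / Kxkur);
      double d_in_inv = 1.0 / ((1.0 + rni) * (1.0 + rni) * (1.0 + rni) +
                               (1.0 + rki) * (1.0 + rki) - 1.0);
      double d_out_inv = 1.0 / ((1.0 + rno) * (1.0 + rno) * (1.0 + rno) +
                                (1.0 + rko) * (1.0 + rko) - 1.0);
      const double atp_f = 1.0 / (1.0 + MgATP / Kmgatp);
      double a1 = k1p * rni * rni * rni * d_in_inv;
      double b1 = k1m * MgADP;
      double a2 = k2p;
      double b2 = k2m * rno * rno * rno * d_out_inv;
      double a3 = k3p * rko * rko * d_out_inv;
      double b3 = k3m * Pfrac * Hp * atp_f;
      double a4 = k4p * (MgATP / Kmgatp) * atp_f;
      double b4 = k4m * rki * rki * d_in_inv;
      double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
      double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
      double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
      double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
      double sxinv = 1.0 / (x1 + x2 + x3 + x4);
      double E1 = x1 * sxinv, E2 = x2 * sxinv, E3 = x3 * sxinv,
             E4 = x4 * sxinv;
      JnakNa = 3.0 * (E1 * a3 - E2 * b3);
      JnakK  = 2.0 * (E4 * b1 - E3 * a1);
      INaK = P.Pnak * (JnakNa + JnakK);
    }
    // background / pump currents
    double IKb  = P.GKb * LK(Q_XKB) * (v - EK);
    double INab = P.PNab * A1 * (nai * expv - nao);
    double ICab = P.PCab * A2 * (cai * exp2v - 0.341 * cao);
    double IpCa = P.GpCa * cai / (0.0005 + cai);

    // SR fluxes
    double JdiffNa = (nass - nai) * 0.5;
    double JdiffK  = (kss - ki) * 0.5;
    double Jdiff   = (cass - cai) * 5.0;
    double inv_cajsr = 1.0 / cajsr;
    double r15 = 1.5 * inv_cajsr;
    double r15_2 = r15 * r15, r15_4 = r15_2 * r15_2;
    double rel_base = 1.0 / (1.0 + r15_4 * r15_4);
    const double bt = 4.75, btp = 1.25 * bt;
    double Jrel_inf  = P.jrel_f * 0.5 * bt * (-ICaL) * rel_base;
    double Jrel_infp = P.jrel_f * 0.5 * btp * (-ICaL) * rel_base;
    double tau_fac = (1.0 + 0.0123 * inv_cajsr);
    double itau_rel  = tau_fac * (1.0 / bt);
    double itau_relp = tau_fac * (1.0 / btp);
    if (itau_rel > 1000.0) itau_rel = 1000.0;   // tau floored at 0.001 ms
    if (itau_relp > 1000.0) itau_relp = 1000.0;
    double Jrel = (1.0 - fp) * s[iJrelnp] + fp * s[iJrelp];
    double Jupnp = P.jup_f * 0.004375 * cai / (cai + 0.00092);
    double Jupp  = P.jup_f * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double Jleak = (0.0039375 / 15.0) * cansr;
    double Jup = (1.0 - fp) * Jupnp + fp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) * 0.01;

    // ICaL ca-dependent gate drive
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double rn = 1.0 + Kmn / cass;
    double rn2 = rn * rn;
    double anca = km2n / (k2n + km2n * rn2 * rn2);

    // ---- derivatives (non-gate states) ----
    double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                  INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Ist;
    double dv = -Itot;
    double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) *
                    Acap / (Frdy * vmyo) + JdiffNa * vss / vmyo;
    double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
    double dki = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) *
                   Acap / (Frdy * vmyo) + JdiffK * vss / vmyo;
    double dkss = -ICaK * Acap / (Frdy * vss) - JdiffK;
    double t1 = (0.00238 + cai); t1 = P.cmdnmax * 0.00238 / (t1 * t1);
    double t2 = (0.0005 + cai);  t2 = 0.07 * 0.0005 / (t2 * t2);
    double Bcai = 1.0 / (1.0 + t1 + t2);
    double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) *
                            Acap / (2.0 * Frdy * vmyo) -
                          Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    double b1t = (0.00087 + cass); b1t = 0.047 * 0.00087 / (b1t * b1t);
    double b2t = (0.0087 + cass);  b2t = 1.124 * 0.0087 / (b2t * b2t);
    double Bcass = 1.0 / (1.0 + b1t + b2t);
    double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) *
                              Acap / (2.0 * Frdy * vss) +
                            Jrel * vjsr / vss - Jdiff);
    double dcansr = Jup - Jtr * vjsr / vnsr;
    double j1 = (0.8 + cajsr); j1 = 10.0 * 0.8 / (j1 * j1);
    double Bcajsr = 1.0 / (1.0 + j1);
    double dcajsr = Bcajsr * (Jtr - Jrel);
    double dCaMKt = aCaMK * CaMKb * (CaMKb + s[iCaMKt]) - bCaMK * s[iCaMKt];
    double dnca = anca * k2n - nca * km2n;
    double dJrelnp = (Jrel_inf - s[iJrelnp]) * itau_rel;
    double dJrelp  = (Jrel_infp - s[iJrelp]) * itau_relp;

    // ---- update ----
    s[iV] += dt * dv;
    s[iNai] += dt * dnai;   s[iNass] += dt * dnass;
    s[iKi] += dt * dki;     s[iKss] += dt * dkss;
    s[iCai] += dt * dcai;   s[iCass] += dt * dcass;
    s[iCansr] += dt * dcansr; s[iCajsr] += dt * dcajsr;
    // positivity floor: the release equations are unprotected as cajsr -> 0
    // and explicit stepping can otherwise push Ca pools (non-physically)
    // below zero during strong release
    if (s[iCai] < 1e-7) s[iCai] = 1e-7;
    if (s[iCass] < 1e-7) s[iCass] = 1e-7;
    if (s[iCansr] < 1e-4) s[iCansr] = 1e-4;
    if (s[iCajsr] < 1e-4) s[iCajsr] = 1e-4;
    s[iNca] += dt * dnca;
    s[iJrelnp] += dt * dJrelnp; s[iJrelp] += dt * dJrelp;
    s[iCaMKt] += dt * dCaMKt;

    if (method == 1) {
      const double *rl0 = &RLTAB[(size_t)ix * NGATE];
      const double *rl1 = rl0 + NGATE;
      bool epi = (P.celltype == 1);
      double idelta = LK(Q_IDELTAEPI);
      for (int g = 0; g < NGATE; g++) {
        double ssg = p0[Q_SS0 + g] + w * (p1[Q_SS0 + g] - p0[Q_SS0 + g]);
        double eg = rl0[g] + w * (rl1[g] - rl0[g]);
        if (epi && (g == 10 || g == 11 || g == 13 || g == 14)) {
          // epi Ito inactivation runs on a slowed clock; fall back to the
          // explicit update with the adjusted rate
          double itau = (p0[Q_ITAU0 + g] + w * (p1[Q_ITAU0 + g] -
                          p0[Q_ITAU0 + g])) * idelta;
          int si = gate_state[g];
          s[si] += dt * (ssg - s[si]) * itau;
        } else {
          int si = gate_state[g];
          s[si] = ssg + (s[si] - ssg) * eg;
        }
      }
    } else {
      bool epi = (P.celltype == 1);
      double idelta = epi ? LK(Q_IDELTAEPI) : 1.0;
      for (int g = 0; g < NGATE; g++) {
        double ssg = p0[Q_SS0 + g] + w * (p1[Q_SS0 + g] - p0[Q_SS0 + g]);
        double itau = p0[Q_ITAU0 + g] + w * (p1[Q_ITAU0 + g] - p0[Q_ITAU0 + g]);
        if (epi && (g == 10 || g == 11 || g == 13 || g == 14)) itau *= idelta;
        int si = gate_state[g];
        s[si] += dt * (ssg - s[si]) * itau;
      }
    }
#undef LK
  }

  NumericVector out_state(NSTATE);
  for (int i = 0; i < NSTATE; i++) out_state[i] = s[i];
  out_state.attr("names") = ord_initial_state_cpp().attr("names");
  return List::create(
    _["state"] = out_state,
    _["time"] = NumericVector(rt.begin(), rt.end()),
    _["vm"] = NumericVector(rv.begin(), rv.end()),
    _["cai"] = NumericVector(rca.begin(), rca.end()),
    _["cajsr"] = NumericVector(rjsr.begin(), rjsr.end()),
    _["blowup"] = blowup,
    _["blowup_time"] = blowup_t);
}
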
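// Human ventricular ionic model (ten Tusscher-type, 2004 formulation) and
// explicit monodomain reaction-diffusion integrator.
//
// One code path serves single cells (1x1 grid, D = 0) and 2D / thin-slab 3D
// tissue.  Voltage-dependent gate steady states and Rush-Larsen decay factors
// are tabulated per run (fixed dt) on a 0.02 mV grid; calcium-dependent gates
// and ionic concentrations are computed directly.  Intracellular and SR
// calcium use the analytic instantaneous-buffer update of the published
// integration scheme.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- physical constants -------------------------------------------------
static const double Rgas = 8314.472;     // mJ/(mol K)
static const double Frdy = 96485.3415;   // C/mol
static const double Temp = 310.0;        // K
static const double RTF  = Rgas * Temp / Frdy;

static const double Ko  = 5.4;    // mM
static const double Cao = 2.0;    // mM
static const double Nao = 140.0;  // mM

static const double Vc  = 0.016404;  // cytoplasmic volume (units of the model)
static const double Vsr = 0.001094;  // SR volume
static const double Cap = 0.185;     // capacitance scaling

static const double Bufc = 0.15,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Kup = 0.00025;
static const double arel = 0.016464, brel = 0.25, crel = 0.008232;
static const double Vleak = 8e-5;
static const double pKNa = 0.03;
static const double KmK = 1.0, KmNa = 40.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncag = 0.35;
static const double KpCa = 0.0005;

// state layout
enum { iV = 0, iM, iH, iJ, iXr1, iXr2, iXs, iR, iS, iD, iF, iFCa, iG,
       iCai, iCaSR, iNai, iKi, NSTATE };

struct TTPars {
  double gNa, gCaL, gto, gKs, gKr, gK1;
  double pNaK, kNaCa, gpCa, gpK, gbNa, gbCa, Vmaxup;
  int celltype; // 0 epi, 1 endo, 2 M
};

static TTPars pars_from_list(const List& p) {
  TTPars q;
  q.gNa = p["g_Na"]; q.gCaL = p["g_CaL"]; q.gto = p["g_to"];
  q.gKs = p["g_Ks"]; q.gKr = p["g_Kr"]; q.gK1 = p["g_K1"];
  q.pNaK = p["p_NaK"]; q.kNaCa = p["k_NaCa"];
  q.gpCa = p["g_pCa"]; q.gpK = p["g_pK"];
  q.gbNa = p["g_bNa"]; q.gbCa = p["g_bCa"];
  q.Vmaxup = p["V_maxup"];
  std::string ct = as<std::string>(p["cell_type"]);
  q.celltype = (ct == "endo") ? 1 : (ct == "M" ? 2 : 0);
  return q;
}

// ---- voltage-dependent quantities --------------------------------------
struct VDep {
  double minf, mrl, hinf, hrl, jinf, jrl;
  double xr1inf, xr1rl, xr2inf, xr2rl, xsinf, xsrl;
  double rinf, rrl, sinf, srl, dinf, drl, finf, frl;
  double icalA;   // 4 V F^2/(RT) / (exp(2VF/RT)-1)   [-> 2F at V=0]
  double icalE;   // exp(2VF/RT)
  double ncxA;    // exp(n VF/RT)       / (1 + ksat exp((n-1)VF/RT))
  double ncxB;    // exp((n-1) VF/RT)   / (1 + ksat exp((n-1)VF/RT))
  double nakrec;  // INaK voltage dependence
  double ipkrec;  // IpK voltage dependence
};

static void vdep_at(double V, double dt, int celltype, VDep& o) {
  double A, B, C, inf, tau;
  // m
  inf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2);
  A = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  B = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.1 / (1.0 + exp((V - 50.0) / 200.0));
  o.minf = inf; o.mrl = exp(-dt / (A * B));
  // h
  inf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2);
  if (V >= -40.0) {
    tau = 1.0 / (0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1))));
  } else {
    A = 0.057 * exp(-(V + 80.0) / 6.8);
    B = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    tau = 1.0 / (A + B);
  }
  o.hinf = inf; o.hrl = exp(-dt / tau);
  // j
  o.jinf = inf;
  if (V >= -40.0) {
    B = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    tau = 1.0 / B;
  } else {
    A = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    B = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    tau = 1.0 / (A + B);
  }
  o.jrl = exp(-dt / tau);
  // xr1
  inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  A = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  B = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  o.xr1inf = inf; o.xr1rl = exp(-dt / (A * B));
  // xr2
  inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  A = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  B = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  o.xr2inf = inf; o.xr2rl = exp(-dt / (A * B));
  // xs
  inf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  A = 1100.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
  B = 1.0 / (1.0 + exp((V - 60.0) / 20.0));
  o.xsinf = inf; o.xsrl = exp(-dt / (A * B));
  // transient outward r and s (cell-type dependent s for endo)
  o.rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  o.rrl = exp(-dt / tau);
  if (celltype == 1) { // endo
    o.sinf = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    tau = 1000.0 * exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {             // epi and M
    o.sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    tau = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
          5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  }
  o.srl = exp(-dt / tau);
  // d
  inf = 1.0 / (1.0 + exp((-5.0 - V) / 7.5));
  A = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  B = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  C = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  o.dinf = inf; o.drl = exp(-dt / (A * B + C));
  // f
  inf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau = 1125.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
        165.0 / (1.0 + exp((25.0 - V) / 10.0));
  o.finf = inf; o.frl = exp(-dt / tau);
  // voltage factors of ICaL, INaCa, INaK, IpK
  double vf = V / RTF;
  double e2 = exp(2.0 * vf);
  o.icalE = e2;
  if (fabs(V) < 1e-6) {
    o.icalA = 2.0 * Frdy; // limit of 4 V F^2/(RT) / (exp(2VF/RT)-1)
  } else {
    o.icalA = 4.0 * V * Frdy / RTF / (e2 - 1.0);
  }
  double eA = exp(ncag * vf), eB = exp((ncag - 1.0) * vf);
  double den = 1.0 + ksat * eB;
  o.ncxA = eA / den; o.ncxB = eB / den;
  o.nakrec = 1.0 / (1.0 + 0.1245 * exp(-0.1 * vf) + 0.0353 * exp(-vf));
  o.ipkrec = 1.0 / (1.0 + exp((25.0 - V) / 5.98));
}

// inward-rectifier steady-state activation, a function of V - EK only
static inline double xk1_inf(double vek) {
  double a = 0.1 / (1.0 + exp(0.06 * (vek - 200.0)));
  double b = (3.0 * exp(0.0002 * (vek + 100.0)) + exp(0.1 * (vek - 10.0))) /
             (1.0 + exp(-0.5 * vek));
  return a / (a + b);
}

// ---- lookup tables ------------------------------------------------------
struct LUT {
  double vmin, vstep, inv_vstep;
  int n;
  std::vector<VDep> tab;
  double ekmin, ekstep, inv_ekstep;
  int nek;
  std::vector<double> k1tab;

  void build(double dt, int celltype) {
    vmin = -120.0; vstep = 0.02; n = (int)((80.0 - vmin) / vstep) + 2;
    inv_vstep = 1.0 / vstep;
    tab.resize(n);
    for (int i = 0; i < n; ++i) vdep_at(vmin + i * vstep, dt, celltype, tab[i]);
    ekmin = -200.0; ekstep = 0.02; nek = (int)((200.0 - ekmin) / ekstep) + 2;
    inv_ekstep = 1.0 / ekstep;
    k1tab.resize(nek);
    for (int i = 0; i < nek; ++i) k1tab[i] = xk1_inf(ekmin + i * ekstep);
  }
  inline const VDep& at(double V) const {
    int i = (int)((V - vmin) * inv_vstep + 0.5);
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    return tab[i];
  }
  inline double k1(double vek) const {
    int i = (int)((vek - ekmin) * inv_ekstep + 0.5);
    if (i < 0) i = 0; if (i >= nek) i = nek - 1;
    return k1tab[i];
  }
};

//' Resting state of the ventricular ionic model
//'
//' The published resting initial conditions (17 state variables: membrane
//' potential, gates, intracellular/SR calcium, sodium and potassium).
//' Useful for building initial-state matrices for [run_monodomain()].
//'
//' @return named numeric vector of length 17.
//' @export
// [[Rcpp::export]]
NumericVector tt_rest_state() {
  NumericVector s(NSTATE);
  s[iV] = -86.2; s[iM] = 0.0; s[iH] = 0.75; s[iJ] = 0.75;
  s[iXr1] = 0.0; s[iXr2] = 1.0; s[iXs] = 0.0;
  s[iR] = 0.0; s[iS] = 1.0; s[iD] = 0.0; s[iF] = 1.0; s[iFCa] = 1.0;
  s[iG] = 1.0; s[iCai] = 0.0002; s[iCaSR] = 0.2;
  s[iNai] = 11.6; s[iKi] = 138.3;
  s.attr("names") = CharacterVector::create(
    "Vm", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "fCa", "g",
    "Cai", "CaSR", "Nai", "Ki");
  return s;
}

struct Stim {
  std::vector<int> nodes;
  double start, end, amp; // amp > 0 depolarizes
};

// Advance one node by one time step.  st points at its NSTATE slot.
// Returns total ionic current (for diagnostics); updates state in place
// except Vm, whose reaction-part increment is written to dv_out.
static inline void step_node(double* st, const LUT& lut, const TTPars& P,
                             double dt, double istim, double* dv_out,
                             double* Es /* cached EK, ENa, EKs, ECa */) {
  double V = st[iV];
  const VDep& vd = lut.at(V);

  // Rush-Larsen gate updates
  st[iM]  = vd.minf  + (st[iM]  - vd.minf)  * vd.mrl;
  st[iH]  = vd.hinf  + (st[iH]  - vd.hinf)  * vd.hrl;
  st[iJ]  = vd.jinf  + (st[iJ]  - vd.jinf)  * vd.jrl;
  st[iXr1] = vd.xr1inf + (st[iXr1] - vd.xr1inf) * vd.xr1rl;
  st[iXr2] = vd.xr2inf + (st[iXr2] - vd.xr2inf) * vd.xr2rl;
  st[iXs] = vd.xsinf + (st[iXs] - vd.xsinf) * vd.xsrl;
  st[iR]  = vd.rinf  + (st[iR]  - vd.rinf)  * vd.rrl;
  st[iS]  = vd.sinf  + (st[iS]  - vd.sinf)  * vd.srl;
  st[iD]  = vd.dinf  + (st[iD]  - vd.dinf)  * vd.drl;
  st[iF]  = vd.finf  + (st[iF]  - vd.finf)  * vd.frl;

  // calcium-dependent gates (tau = 2 ms, Euler with the published lock rule)
  double Cai = st[iCai];
  double t = Cai / 0.000325, t2 = t * t, t4 = t2 * t2, t8 = t4 * t4;
  double afca = 1.0 / (1.0 + t8);
  double bfca = 0.1 / (1.0 + exp((Cai - 0.0005) / 0.0001));
  double cfca = 0.2 / (1.0 + exp((Cai - 0.00075) / 0.0008));
  double fcainf = (afca + bfca + cfca + 0.23) / 1.46;
  double fcanew = st[iFCa] + dt * (fcainf - st[iFCa]) / 2.0;
  if (!(fcainf > st[iFCa] && V > -60.0)) st[iFCa] = fcanew;
  double u = Cai / 0.00035, u2 = u * u, u4 = u2 * u2, u6 = u4 * u2;
  double ginf;
  if (Cai < 0.00035) ginf = 1.0 / (1.0 + u6);
  else { double u8 = u4 * u4, u16 = u8 * u8; ginf = 1.0 / (1.0 + u16); }
  double gnew = st[iG] + dt * (ginf - st[iG]) / 2.0;
  if (!(ginf > st[iG] && V > -60.0)) st[iG] = gnew;

  double EK = Es[0], ENa = Es[1], EKs = Es[2], ECa = Es[3];
  double Nai = st[iNai];

  // currents (pA/pF)
  double INa = P.gNa * st[iM] * st[iM] * st[iM] * st[iH] * st[iJ] * (V - ENa);
  double ICaL = P.gCaL * st[iD] * st[iF] * st[iFCa] * vd.icalA *
                (Cai * vd.icalE - 0.341 * Cao);
  double Ito = P.gto * st[iR] * st[iS] * (V - EK);
  double IKr = P.gKr * sqrt(Ko / 5.4) * st[iXr1] * st[iXr2] * (V - EK);
  double IKs = P.gKs * st[iXs] * st[iXs] * (V - EKs);
  double IK1 = P.gK1 * lut.k1(V - EK) * (V - EK);
  double Nai3 = Nai * Nai * Nai;
  double INaCa = P.kNaCa *
    (vd.ncxA * Nai3 * Cao - vd.ncxB * Nao * Nao * Nao * Cai * 2.5) /
    ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao));
  double INaK = P.pNaK * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) * vd.nakrec;
  double IpCa = P.gpCa * Cai / (KpCa + Cai);
  double IpK = P.gpK * vd.ipkrec * (V - EK);
  double IbNa = P.gbNa * (V - ENa);
  double IbCa = P.gbCa * (V - ECa);

  double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa +
                IpK + IbNa + IbCa;
  *dv_out = -dt * (Iion - istim);

  // calcium handling with analytic instantaneous buffering
  double CaSR = st[iCaSR];
  double Irel = (arel * CaSR * CaSR / (brel * brel + CaSR * CaSR) + crel) *
                st[iD] * st[iG];
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = P.Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double casrcur = Iup - Irel - Ileak;
  double cacur = -(ICaL + IbCa + IpCa - 2.0 * INaCa) * Cap / (2.0 * Vc * Frdy);

  double cacsqn = Bufsr * CaSR / (CaSR + Kbufsr);
  double dcasr = dt * (Vc / Vsr) * casrcur;
  double bj = Bufsr - cacsqn - dcasr - CaSR + Kbufsr;
  double cj = Kbufsr * (cacsqn + dcasr + CaSR);
  st[iCaSR] = (sqrt(bj * bj + 4.0 * cj) - bj) / 2.0;

  double cabuf = Bufc * Cai / (Cai + Kbufc);
  double dcai = dt * (cacur - casrcur);
  double bc = Bufc - cabuf - dcai - Cai + Kbufc;
  double cc = Kbufc * (cabuf + dcai + Cai);
  st[iCai] = (sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  st[iNai] += -dt * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cap / (Vc * Frdy);
  st[iKi]  += -dt * (-istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
              Cap / (Vc * Frdy);
}

// [[Rcpp::export]]
List tt_monodomain(IntegerVector dims, double dx, double Dcoef, List pars,
                   NumericMatrix state0, List stims,
                   double duration, double dt, double record_every,
                   bool passive = false) {
  int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
      nz = dims.size() > 2 ? dims[2] : 1;
  int nn = nx * ny * nz;
  if (state0.nrow() != nn || state0.ncol() != NSTATE)
    stop("state matrix must be n_nodes x %d", NSTATE);

  TTPars P = pars_from_list(pars);
  LUT lut;
  lut.build(dt, P.celltype);

  std::vector<Stim> sv;
  for (int k = 0; k < stims.size(); ++k) {
    List s = stims[k];
    Stim st;
    IntegerVector nodes = s["nodes"];
    st.nodes.assign(nodes.begin(), nodes.end()); // 0-based
    st.start = s["start"]; st.end = st.start + as<double>(s["duration"]);
    st.amp = s["amplitude"];
    sv.push_back(st);
  }

  long nsteps = (long)std::llround(duration / dt);
  int rec_stride = std::max(1, (int)std::llround(record_every / dt));
  int nframes = (int)(nsteps / rec_stride) + 1;

  NumericMatrix vmrec(nn, nframes), cairec(nn, nframes);
  NumericVector trec(nframes);

  // node-major storage: all NSTATE components of a node are contiguous
  std::vector<double> S((size_t)nn * NSTATE);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < NSTATE; ++c) S[(size_t)i * NSTATE + c] = state0(i, c);
  auto SP = [&](int node, int comp) -> double& {
    return S[(size_t)node * NSTATE + comp];
  };

  std::vector<double> istim(nn, 0.0), dv(nn, 0.0);
  std::vector<double> Ecache(4 * nn);
  double rdx2 = Dcoef / (dx * dx);

  // record frame 0
  for (int i = 0; i < nn; ++i) { vmrec(i, 0) = SP(i, iV); cairec(i, 0) = SP(i, iCai); }
  trec[0] = 0.0;
  int frame = 1;

  for (long stp = 0; stp < nsteps; ++stp) {
    double tnow = stp * dt;
    if (stp % 5000 == 0) Rcpp::checkUserInterrupt();

    // stimulus currents
    bool anystim = false;
    for (size_t k = 0; k < sv.size(); ++k)
      if (tnow >= sv[k].start && tnow < sv[k].end) { anystim = true; break; }
    if (anystim) std::fill(istim.begin(), istim.end(), 0.0);
    for (size_t k = 0; k < sv.size(); ++k) {
      const Stim& s = sv[k];
      if (tnow >= s.start && tnow < s.end)
        for (size_t q = 0; q < s.nodes.size(); ++q) istim[s.nodes[q]] += s.amp;
    }

    if (!passive) {
      if (stp % 25 == 0) { // refresh slowly varying Nernst potentials
        for (int i = 0; i < nn; ++i) {
          double Nai = SP(i, iNai), Ki = SP(i, iKi), Cai = SP(i, iCai);
          Ecache[4 * i + 0] = RTF * log(Ko / Ki);
          Ecache[4 * i + 1] = RTF * log(Nao / Nai);
          Ecache[4 * i + 2] = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
          Ecache[4 * i + 3] = 0.5 * RTF * log(Cao / Cai);
        }
      }
      for (int i = 0; i < nn; ++i) {
        double dvi;
        step_node(&S[(size_t)i * NSTATE], lut, P, dt,
                  anystim ? istim[i] : 0.0, &dvi, &Ecache[4 * i]);
        dv[i] = dvi;
      }
    } else {
      for (int i = 0; i < nn; ++i)
        dv[i] = dt * (anystim ? istim[i] : 0.0);
    }

    // diffusion with no-flux (mirror) boundaries
    if (Dcoef > 0.0 && nn > 1) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = x + nx * (y + ny * z);
            double v = SP(i, iV), lap = 0.0;
            lap += ((x > 0)      ? SP(i - 1, iV)       : v) - v;
            lap += ((x < nx - 1) ? SP(i + 1, iV)       : v) - v;
            if (ny > 1) {
              lap += ((y > 0)      ? SP(i - nx, iV)    : v) - v;
              lap += ((y < ny - 1) ? SP(i + nx, iV)    : v) - v;
            }
            if (nz > 1) {
              lap += ((z > 0)      ? SP(i - nx * ny, iV) : v) - v;
              lap += ((z < nz - 1) ? SP(i + nx * ny, iV) : v) - v;
            }
            dv[i] += dt * rdx2 * lap;
          }
    }

    for (int i = 0; i < nn; ++i) {
      double vnew = SP(i, iV) + dv[i];
      if (!std::isfinite(vnew) || fabs(vnew) > 200.0)
        stop("integration failure: |Vm| > 200 mV or non-finite at t = %.3f ms (node %d)",
             tnow, i + 1);
      SP(i, iV) = vnew;
    }

    if ((stp + 1) % rec_stride == 0 && frame < nframes) {
      for (int i = 0; i < nn; ++i) {
        vmrec(i, frame) = SP(i, iV); cairec(i, frame) = SP(i, iCai);
      }
      trec[frame] = (stp + 1) * dt;
      ++frame;
    }
  }

  NumericMatrix stateout(nn, NSTATE);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < NSTATE; ++c) stateout(i, c) = S[(size_t)i * NSTATE + c];
  return List::create(_["time"] = trec, _["vm"] = vmrec, _["cai"] = cairec,
                      _["state"] = stateout, _["n_frames"] = frame);
}
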
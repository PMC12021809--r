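// Monodomain reaction-diffusion solver with the Courtemanche-Ramirez-Nattel
// human atrial myocyte model (1998), vectorized over an arbitrary node set
// (1D strands, 2D sheets, coupled sheet pairs via explicit edge lists).
//
// Integration: operator splitting. The reaction step uses Rush-Larsen for
// the 12 voltage-gated variables (via V-indexed lookup tables of the gate
// steady states and exp(-dt/tau)) and forward Euler for V and the
// concentrations; diffusion is an explicit step on the edge graph every
// n_sub reaction steps. Conductance scalings (g_Na, g_K1, g_to, g_Kur,
// g_CaL) are per-node multipliers, so fibrotic/AF remodeling is spatial.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// physical constants and cell geometry (Courtemanche 1998)
static const double Rgas = 8.3143, Temp = 310.0, Frdy = 96.4867;
static const double Cm = 100.0;               // pF
static const double Vi_ = 13668.0, Vup_ = 1109.52, Vrel_ = 96.48; // um^3
static const double Ko = 5.4, Nao = 140.0, Cao = 1.8;             // mM
static const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
static const double gKr = 0.0294117647, gKs = 0.12941176, gCaL = 0.12375;
static const double gbCa = 0.001131, gbNa = 0.0006744375;
static const double INaKmax = 0.59933874, KmNai = 10.0, KmKo = 1.5;
static const double INaCamax = 1600.0, KmNa = 87.5, KmCa = 1.38;
static const double ksat = 0.1, gam = 0.35;
static const double IpCamax = 0.275;
static const double Iupmax = 0.005, Kup = 0.00092, Caupmax = 15.0;
static const double krel = 30.0, tau_tr = 180.0;
static const double CMDNmax = 0.05, TRPNmax = 0.07, CSQNmax = 10.0;
static const double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;
static const double KQ10 = 3.0;

static const int NGATE = 12; // m h j oa oi ua ui xr xs d f w
enum { G_M, G_H, G_J, G_OA, G_OI, G_UA, G_UI, G_XR, G_XS, G_D, G_F, G_W };

// state layout (rows of the state matrix)
enum {
  S_V, S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI, S_XR, S_XS, S_D, S_F,
  S_FCA, S_U, S_VG, S_W, S_NAI, S_KI, S_CAI, S_CAUP, S_CAREL, NSTATE
};

// V-dependent quantities, interleaved row-per-voltage for cache locality:
// 12 gate steady states, 12 Rush-Larsen blend factors 1-exp(-dt/tau),
// then k1f, krf, kurg, fnak, expg, expg1.
static const int TCOL = 2 * NGATE + 6;
enum { C_K1F = 2 * NGATE, C_KRF, C_KURG, C_FNAK, C_EXPG, C_EXPG1 };
struct Tables {
  double vmin, dv;
  int n;
  std::vector<double> flat; // n rows of TCOL
};

static void gate_rates(double V, double *inf, double *tau) {
  // INa gates
  double am = (std::fabs(V + 47.13) < 1e-6)
    ? 3.2 : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  inf[G_M] = am / (am + bm); tau[G_M] = 1.0 / (am + bm);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[G_H] = ah / (ah + bh); tau[G_H] = 1.0 / (ah + bh);
  inf[G_J] = aj / (aj + bj); tau[G_J] = 1.0 / (aj + bj);
  // Ito gates
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[G_OA] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  tau[G_OA] = 1.0 / ((aoa + boa) * KQ10);
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  inf[G_OI] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[G_OI] = 1.0 / ((aoi + boi) * KQ10);
  // IKur gates
  double aua = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double bua = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[G_UA] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  tau[G_UA] = 1.0 / ((aua + bua) * KQ10);
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  inf[G_UI] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  tau[G_UI] = 1.0 / ((aui + bui) * KQ10);
  // IKr, IKs activation
  double axr = (std::fabs(V + 14.1) < 1e-6)
    ? 0.0015 : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double bxr = (std::fabs(V - 3.3328) < 1e-6)
    ? 3.7866e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  inf[G_XR] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  tau[G_XR] = 1.0 / (axr + bxr);
  double axs = (std::fabs(V - 19.9) < 1e-6)
    ? 6.8e-4 : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double bxs = (std::fabs(V - 19.9) < 1e-6)
    ? 3.15e-4 : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  inf[G_XS] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  tau[G_XS] = 0.5 / (axs + bxs);
  // ICaL gates
  inf[G_D] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  tau[G_D] = (std::fabs(V + 10.0) < 1e-6)
    ? 2.28937728938
    : (1.0 - std::exp(-(V + 10.0) / 6.24)) /
      (0.035 * (V + 10.0) * (1.0 + std::exp(-(V + 10.0) / 6.24)));
  inf[G_F] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[G_F] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  // SR release window gate w
  inf[G_W] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  tau[G_W] = (std::fabs(V - 7.9) < 1e-6)
    ? 0.923076923
    : 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
      ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));
}

static Tables build_tables(double dt) {
  Tables tb;
  tb.vmin = -120.0; tb.dv = 0.02;
  tb.n = (int)std::floor((120.0 - tb.vmin) / tb.dv) + 2;
  tb.flat.resize((size_t)tb.n * TCOL);
  double sig_nak = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double inf[NGATE], tau[NGATE];
  for (int i = 0; i < tb.n; ++i) {
    double V = tb.vmin + i * tb.dv;
    double *row = &tb.flat[(size_t)i * TCOL];
    gate_rates(V, inf, tau);
    for (int g = 0; g < NGATE; ++g) {
      row[g] = inf[g];
      row[NGATE + g] = 1.0 - std::exp(-dt / tau[g]); // blend factor
    }
    double fvrt = Frdy * V / (Rgas * Temp);
    row[C_K1F] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
    row[C_KRF] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
    row[C_KURG] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
    row[C_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * fvrt) +
                         0.0365 * sig_nak * std::exp(-fvrt));
    row[C_EXPG] = std::exp(gam * fvrt);
    row[C_EXPG1] = std::exp((gam - 1.0) * fvrt);
  }
  return tb;
}

struct Interp {
  const double *r0; double w;
};
static inline Interp locate(const Tables &tb, double V) {
  double x = (V - tb.vmin) / tb.dv;
  if (x < 0.0) x = 0.0;
  if (x > tb.n - 2) x = tb.n - 2;
  int i = (int)x;
  Interp p; p.r0 = &tb.flat[(size_t)i * TCOL]; p.w = x - i;
  return p;
}
static inline double look(const Interp &p, int col) {
  return p.r0[col] + p.w * (p.r0[col + TCOL] - p.r0[col]);
}

// default resting state of the (unmodified) model
// [[Rcpp::export]]
NumericVector courtemanche_rest_cpp() {
  NumericVector s(NSTATE);
  s[S_V] = -81.18; s[S_M] = 0.002908; s[S_H] = 0.9649; s[S_J] = 0.9775;
  s[S_OA] = 0.03043; s[S_OI] = 0.9992; s[S_UA] = 0.004966; s[S_UI] = 0.9986;
  s[S_XR] = 3.296e-5; s[S_XS] = 0.01869; s[S_D] = 1.367e-4; s[S_F] = 0.9996;
  s[S_FCA] = 0.7755; s[S_U] = 0.0; s[S_VG] = 1.0; s[S_W] = 0.9992;
  s[S_NAI] = 11.17; s[S_KI] = 139.0; s[S_CAI] = 1.013e-4;
  s[S_CAUP] = 1.488; s[S_CAREL] = 1.488;
  return s;
}

// [[Rcpp::export]]
List run_monodomain_cpp(NumericMatrix state0,      // NSTATE x n_nodes
                        NumericMatrix scaling,     // n_nodes x 5
                        LogicalVector conducting,
                        IntegerMatrix edges,       // E x 2 (0-based)
                        NumericVector edge_w,      // coupling 1/ms
                        double dt, int n_sub, double duration,
                        double record_dt,
                        IntegerVector stim_nodes,  // 0-based
                        double stim_start, double stim_dur,
                        double stim_period, int stim_count, double stim_amp,
                        double act_threshold,
                        int state_record_stride,  // 0 = off
                        double quiet_exit_ms) {   // 0 = off
  const int n = state0.ncol();
  if (state0.nrow() != NSTATE) stop("state matrix must have 21 rows");
  Tables tb = build_tables(dt);
  const double fca_rl = 1.0 - std::exp(-dt / 2.0);
  const double u_rl = 1.0 - std::exp(-dt / 8.0);

  std::vector<double> S(state0.begin(), state0.end()); // column-major
  std::vector<int> cond_idx;
  for (int i = 0; i < n; ++i) if (conducting[i]) cond_idx.push_back(i);

  // Nernst potentials and the INaK Nai factor involve log/pow of slowly
  // drifting concentrations; refresh them on a ~0.5 ms cadence
  std::vector<double> cENa(n), cEK(n), cECa(n), cNaKf(n);
  const long nernst_every = std::max(1L, (long)std::llround(0.5 / dt));
  std::vector<double> scal(5 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 5; ++k) scal[(size_t)i * 5 + k] = scaling(i, k);
  std::vector<double> dv(n, 0.0);
  std::vector<char> is_stim(n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int s = stim_nodes[k];
    if (s >= 0 && s < n) is_stim[s] = 1;
  }
  const double rtf = Rgas * Temp / Frdy;

  const long n_steps = (long)std::llround(duration / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const int n_frames = (int)(n_steps / rec_every) + 1;
  NumericMatrix vtrace(n, n_frames);
  NumericVector first_act(n, -1.0), last_act(n, -1.0);
  IntegerVector n_up(n, 0);
  std::vector<double> vprev(n);
  for (int i = 0; i < n; ++i) vprev[i] = S[(size_t)i * NSTATE + S_V];

  int n_state_frames = 0;
  NumericMatrix strace;
  if (state_record_stride > 0) {
    n_state_frames = (int)(n_steps / (rec_every * state_record_stride)) + 1;
    strace = NumericMatrix(NSTATE, n_state_frames * n); // per frame blocks
  }

  int frame = 0, sframe = 0;
  // record initial frame
  for (int i = 0; i < n; ++i) vtrace(i, 0) = vprev[i];
  if (state_record_stride > 0) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < NSTATE; ++k) strace(k, 0 * n + i) = S[(size_t)i * NSTATE + k];
    sframe = 1;
  }
  frame = 1;

  const int n_edges = edges.nrow();
  std::vector<int> ea(n_edges), eb(n_edges);
  std::vector<double> ew(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    ea[e] = edges(e, 0); eb[e] = edges(e, 1); ew[e] = edge_w[e];
  }
  bool unstable = false; long bad_step = -1; int bad_node = -1;

  for (long step = 0; step < n_steps; ++step) {
    double t = step * dt;
    // stimulus window?
    double amp_now = 0.0;
    if (stim_nodes.size() > 0 && t >= stim_start) {
      double rel = t - stim_start;
      if (stim_period > 0.0) {
        double k = std::floor(rel / stim_period);
        if (k < stim_count && rel - k * stim_period < stim_dur) amp_now = stim_amp;
      } else if (rel < stim_dur) {
        amp_now = stim_amp;
      }
    }

    // refresh cached concentration-dependent terms
    if (step % nernst_every == 0) {
      for (size_t ci = 0; ci < cond_idx.size(); ++ci) {
        int i = cond_idx[ci];
        double *s = &S[(size_t)i * NSTATE];
        cENa[i] = rtf * std::log(Nao / s[S_NAI]);
        cEK[i] = rtf * std::log(Ko / s[S_KI]);
        cECa[i] = 0.5 * rtf * std::log(Cao / s[S_CAI]);
        cNaKf[i] = 1.0 / (1.0 + std::pow(KmNai / s[S_NAI], 1.5)) *
          (Ko / (Ko + KmKo));
      }
    }

    // ---- reaction step on conducting nodes ----
    for (size_t ci = 0; ci < cond_idx.size(); ++ci) {
      int i = cond_idx[ci];
      double *s = &S[(size_t)i * NSTATE];
      double V = s[S_V];
      Interp p = locate(tb, V);
      const double *sc = &scal[(size_t)i * 5];
      const double s_na = sc[0], s_k1 = sc[1];
      const double s_to = sc[2], s_kur = sc[3];
      const double s_cal = sc[4];
      const double Nai = s[S_NAI], Cai = s[S_CAI];
      const double ENa = cENa[i], EK = cEK[i], ECa = cECa[i];

      const double INa = gNa * s_na * s[S_M] * s[S_M] * s[S_M] * s[S_H] * s[S_J] * (V - ENa);
      const double IK1 = gK1 * s_k1 * (V - EK) * look(p, C_K1F);
      const double Ito = gto * s_to * s[S_OA] * s[S_OA] * s[S_OA] * s[S_OI] * (V - EK);
      const double IKur = s_kur * look(p, C_KURG) * s[S_UA] * s[S_UA] * s[S_UA] * s[S_UI] * (V - EK);
      const double IKr = gKr * s[S_XR] * (V - EK) * look(p, C_KRF);
      const double IKs = gKs * s[S_XS] * s[S_XS] * (V - EK);
      const double ICaL = gCaL * s_cal * s[S_D] * s[S_F] * s[S_FCA] * (V - 65.0);
      const double IpCa = IpCamax * Cai / (0.0005 + Cai);
      const double INaK = INaKmax * look(p, C_FNAK) * cNaKf[i];
      const double eg = look(p, C_EXPG), eg1 = look(p, C_EXPG1);
      const double INaCa = INaCamax *
        (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai) /
        ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + ksat * eg1));
      const double IbNa = gbNa * (V - ENa);
      const double IbCa = gbCa * (V - ECa);

      // SR calcium handling
      const double Irel = krel * s[S_U] * s[S_U] * s[S_VG] * s[S_W] * (s[S_CAREL] - Cai);
      const double Itr = (s[S_CAUP] - s[S_CAREL]) / tau_tr;
      const double Iup = Iupmax / (1.0 + Kup / Cai);
      const double Iupleak = Iupmax * s[S_CAUP] / Caupmax;
      const double Fn = 1e-12 * Vrel_ * Irel -
        (5e-13 / Frdy) * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
      const double u_inf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
      const double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
      const double tau_v = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));

      // Rush-Larsen gate updates from the tables
      s[S_M] += (look(p, G_M) - s[S_M]) * look(p, NGATE + G_M);
      s[S_H] += (look(p, G_H) - s[S_H]) * look(p, NGATE + G_H);
      s[S_J] += (look(p, G_J) - s[S_J]) * look(p, NGATE + G_J);
      s[S_OA] += (look(p, G_OA) - s[S_OA]) * look(p, NGATE + G_OA);
      s[S_OI] += (look(p, G_OI) - s[S_OI]) * look(p, NGATE + G_OI);
      s[S_UA] += (look(p, G_UA) - s[S_UA]) * look(p, NGATE + G_UA);
      s[S_UI] += (look(p, G_UI) - s[S_UI]) * look(p, NGATE + G_UI);
      s[S_XR] += (look(p, G_XR) - s[S_XR]) * look(p, NGATE + G_XR);
      s[S_XS] += (look(p, G_XS) - s[S_XS]) * look(p, NGATE + G_XS);
      s[S_D] += (look(p, G_D) - s[S_D]) * look(p, NGATE + G_D);
      s[S_F] += (look(p, G_F) - s[S_F]) * look(p, NGATE + G_F);
      s[S_W] += (look(p, G_W) - s[S_W]) * look(p, NGATE + G_W);
      s[S_FCA] += (1.0 / (1.0 + Cai / 0.00035) - s[S_FCA]) * fca_rl;
      s[S_U] += (u_inf - s[S_U]) * u_rl;
      s[S_VG] += (v_inf - s[S_VG]) * (1.0 - std::exp(-dt / tau_v));

      // concentrations (forward Euler)
      s[S_NAI] += dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (Frdy * Vi_);
      s[S_KI] += dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (Frdy * Vi_);
      const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * Frdy * Vi_) +
        (Vup_ * (Iupleak - Iup) + Irel * Vrel_) / Vi_;
      const double B2 = 1.0 + TRPNmax * KmTrpn / ((Cai + KmTrpn) * (Cai + KmTrpn)) +
        CMDNmax * KmCmdn / ((Cai + KmCmdn) * (Cai + KmCmdn));
      s[S_CAI] += dt * B1 / B2;
      s[S_CAUP] += dt * (Iup - Iupleak - Itr * Vrel_ / Vup_);
      s[S_CAREL] += dt * (Itr - Irel) /
        (1.0 + CSQNmax * KmCsqn / ((s[S_CAREL] + KmCsqn) * (s[S_CAREL] + KmCsqn)));
      if (s[S_CAI] < 1e-7) s[S_CAI] = 1e-7;

      double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa +
        INaK + INaCa + IbNa + IbCa;
      const double stim_i = (amp_now != 0.0 && is_stim[i]) ? amp_now : 0.0;
      s[S_V] = V + dt * (-Iion + stim_i);
    }

    // ---- diffusion step every n_sub reaction steps ----
    if ((step + 1) % n_sub == 0) {
      const double dt_dif = dt * n_sub;
      std::fill(dv.begin(), dv.end(), 0.0);
      for (int e = 0; e < n_edges; ++e) {
        const int a = ea[e], b = eb[e];
        const double f = ew[e] *
          (S[(size_t)b * NSTATE + S_V] - S[(size_t)a * NSTATE + S_V]);
        dv[a] += f; dv[b] -= f;
      }
      for (size_t ci = 0; ci < cond_idx.size(); ++ci) {
        int i = cond_idx[ci];
        S[(size_t)i * NSTATE + S_V] += dt_dif * dv[i];
      }
      // stability guard
      for (size_t ci = 0; ci < cond_idx.size(); ++ci) {
        int i = cond_idx[ci];
        double v = S[(size_t)i * NSTATE + S_V];
        if (!std::isfinite(v) || std::fabs(v) > 200.0) {
          unstable = true; bad_step = step; bad_node = i; break;
        }
      }
      if (unstable) break;
    }

    // ---- activation detection and recording ----
    double tnow = (step + 1) * dt;
    double last_any = -1.0, vmax_now = -1e9;
    for (size_t ci = 0; ci < cond_idx.size(); ++ci) {
      int i = cond_idx[ci];
      double v = S[(size_t)i * NSTATE + S_V];
      if (vprev[i] < act_threshold && v >= act_threshold) {
        if (first_act[i] < 0) first_act[i] = tnow;
        last_act[i] = tnow;
        n_up[i] += 1;
      }
      vprev[i] = v;
      if (last_act[i] > last_any) last_any = last_act[i];
      if (v > vmax_now) vmax_now = v;
    }
    // all tissue repolarized and quiet for a full window: nothing more can
    // happen in a deterministic run, so stop integrating early
    if (quiet_exit_ms > 0.0 && vmax_now < -60.0 &&
        (last_any < 0 ? tnow : tnow - last_any) > quiet_exit_ms) {
      while (frame < n_frames) {
        for (int i = 0; i < n; ++i) vtrace(i, frame) = S[(size_t)i * NSTATE + S_V];
        ++frame;
      }
      break;
    }
    if ((step + 1) % rec_every == 0 && frame < n_frames) {
      for (int i = 0; i < n; ++i) vtrace(i, frame) = S[(size_t)i * NSTATE + S_V];
      if (state_record_stride > 0 && (frame % state_record_stride == 0) &&
          sframe < n_state_frames) {
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < NSTATE; ++k)
            strace(k, sframe * n + i) = S[(size_t)i * NSTATE + k];
        ++sframe;
      }
      ++frame;
    }
  }

  NumericMatrix final_state(NSTATE, n);
  std::copy(S.begin(), S.end(), final_state.begin());
  List out = List::create(
    _["voltage"] = vtrace, _["first_activation"] = first_act,
    _["last_activation"] = last_act, _["upstrokes"] = n_up,
    _["final_state"] = final_state, _["n_frames_filled"] = frame,
    _["unstable"] = unstable, _["bad_step"] = bad_step,
    _["bad_node"] = bad_node + 1);
  if (state_record_stride > 0) {
    out["state_trace"] = strace;
    out["n_state_frames"] = sframe;
  }
  return out;
}
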
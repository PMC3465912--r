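// Coupled-time-loop engine: 2D Ca2+ reaction-diffusion sheet with stochastic
// RyR cluster / rogue-channel gating, driving the whole-cell ventricular AP
// model through the summed release flux.  Mirrors the R module functions
// (step_field, advance_states, cell_currents/step_cell) operation for
// operation; the R versions are the readable reference, this is the
// performance path used by run_protocol().

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic, platform-independent RNG (splitmix64 core)
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------
struct CellPars {
  double Rgas, Temp, Faraday, Cm, V_c, V_sr, V_ss, K_o, Na_o, Ca_o;
  double G_Na, G_K1, G_to, G_Kr, G_Ks, G_CaL, G_bNa, G_bCa, G_pCa, K_pCa,
      G_pK, P_NaK, K_mK, K_mNa, k_NaCa, K_mNai, K_mCa, k_sat, gamma, alpha,
      p_KNa, V_max_pump, K_up, V_leak, V_xfer, Buf_c, K_buf_c, Buf_sr,
      K_buf_sr, Buf_ss, K_buf_ss;
};

static double getp(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

static CellPars read_cell_pars(const List& mp) {
  CellPars p;
  p.Rgas = getp(mp, "Rgas"); p.Temp = getp(mp, "Temp");
  p.Faraday = getp(mp, "Faraday"); p.Cm = getp(mp, "Cm");
  p.V_c = getp(mp, "V_c"); p.V_sr = getp(mp, "V_sr"); p.V_ss = getp(mp, "V_ss");
  p.K_o = getp(mp, "K_o"); p.Na_o = getp(mp, "Na_o"); p.Ca_o = getp(mp, "Ca_o");
  p.G_Na = getp(mp, "G_Na"); p.G_K1 = getp(mp, "G_K1"); p.G_to = getp(mp, "G_to");
  p.G_Kr = getp(mp, "G_Kr"); p.G_Ks = getp(mp, "G_Ks"); p.G_CaL = getp(mp, "G_CaL");
  p.G_bNa = getp(mp, "G_bNa"); p.G_bCa = getp(mp, "G_bCa");
  p.G_pCa = getp(mp, "G_pCa"); p.K_pCa = getp(mp, "K_pCa");
  p.G_pK = getp(mp, "G_pK"); p.P_NaK = getp(mp, "P_NaK");
  p.K_mK = getp(mp, "K_mK"); p.K_mNa = getp(mp, "K_mNa");
  p.k_NaCa = getp(mp, "k_NaCa"); p.K_mNai = getp(mp, "K_mNai");
  p.K_mCa = getp(mp, "K_mCa"); p.k_sat = getp(mp, "k_sat");
  p.gamma = getp(mp, "gamma"); p.alpha = getp(mp, "alpha");
  p.p_KNa = getp(mp, "p_KNa"); p.V_max_pump = getp(mp, "V_max_pump");
  p.K_up = getp(mp, "K_up"); p.V_leak = getp(mp, "V_leak");
  p.V_xfer = getp(mp, "V_xfer"); p.Buf_c = getp(mp, "Buf_c");
  p.K_buf_c = getp(mp, "K_buf_c"); p.Buf_sr = getp(mp, "Buf_sr");
  p.K_buf_sr = getp(mp, "K_buf_sr"); p.Buf_ss = getp(mp, "Buf_ss");
  p.K_buf_ss = getp(mp, "K_buf_ss");
  return p;
}

// state indices
enum { iV = 0, im, ih, ij, id, if_, if2, ifcass, ir, is_, ixr1, ixr2, ixs,
       iNai, iKi, iCai, iCaSS, iCaSR, NSTATE };

struct Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa, IpK, IbNa, IbCa;
  double total() const {
    return INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa + IpK +
           IbNa + IbCa;
  }
};

static Currents cell_currents(const double* st, const CellPars& p,
                              double g_na_scale) {
  Currents c;
  const double V = st[iV], Nai = st[iNai], Ki = st[iKi], Cai = st[iCai],
               CaSS = st[iCaSS];
  const double rtf = p.Rgas * p.Temp / p.Faraday;
  const double ENa = rtf * std::log(p.Na_o / Nai);
  const double EK = rtf * std::log(p.K_o / Ki);
  const double EKs =
      rtf * std::log((p.K_o + p.p_KNa * p.Na_o) / (Ki + p.p_KNa * Nai));
  const double ECa = 0.5 * rtf * std::log(p.Ca_o / Cai);
  c.INa = g_na_scale * p.G_Na * st[im] * st[im] * st[im] * st[ih] * st[ij] *
          (V - ENa);
  const double z = 2.0 * (V - 15.0) / rtf;
  const double ez = std::exp(z);
  double drive;
  if (std::fabs(z) < 1e-7)
    drive = (0.25 * CaSS * ez - p.Ca_o) * (1.0 - z / 2.0);
  else
    drive = (0.25 * CaSS * ez - p.Ca_o) * z / (ez - 1.0);
  c.ICaL = p.G_CaL * st[id] * st[if_] * st[if2] * st[ifcass] * 2.0 *
           p.Faraday * drive;
  c.Ito = p.G_to * st[ir] * st[is_] * (V - EK);
  c.IKr = p.G_Kr * std::sqrt(p.K_o / 5.4) * st[ixr1] * st[ixr2] * (V - EK);
  c.IKs = p.G_Ks * st[ixs] * st[ixs] * (V - EKs);
  const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bk1 =
      (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
       std::exp(0.1 * (V - EK - 10.0))) /
      (1.0 + std::exp(-0.5 * (V - EK)));
  c.IK1 = p.G_K1 * std::sqrt(p.K_o / 5.4) * ak1 / (ak1 + bk1) * (V - EK);
  const double efrac = std::exp(p.gamma * V / rtf);
  const double efrac1 = std::exp((p.gamma - 1.0) * V / rtf);
  c.INaCa = p.k_NaCa *
            (efrac * Nai * Nai * Nai * p.Ca_o -
             efrac1 * p.Na_o * p.Na_o * p.Na_o * Cai * p.alpha) /
            ((p.K_mNai * p.K_mNai * p.K_mNai + p.Na_o * p.Na_o * p.Na_o) *
             (p.K_mCa + p.Ca_o) * (1.0 + p.k_sat * efrac1));
  c.INaK = p.P_NaK * p.K_o * Nai /
           ((p.K_o + p.K_mK) * (Nai + p.K_mNa) *
            (1.0 + 0.1245 * std::exp(-0.1 * V / rtf) +
             0.0353 * std::exp(-V / rtf)));
  c.IpCa = p.G_pCa * Cai / (Cai + p.K_pCa);
  c.IpK = p.G_pK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IbNa = p.G_bNa * (V - ENa);
  c.IbCa = p.G_bCa * (V - ECa);
  return c;
}

static inline double rl_update(double y, double yinf, double tau, double dt) {
  return yinf + (y - yinf) * std::exp(-dt / tau);
}

static inline double buffer_root(double cfree, double Btot, double K,
                                 double d) {
  const double bound = Btot * cfree / (cfree + K);
  const double b = Btot - bound - d - cfree + K;
  const double cc = K * (bound + d + cfree);
  return (std::sqrt(b * b + 4.0 * cc) - b) / 2.0;
}

// one forward-Euler / Rush-Larsen step; identical maths to R step_cell()
static Currents step_cell_cpp(double* st, double j_rel, double i_stim,
                              const CellPars& p, double dt,
                              double g_na_scale) {
  const Currents cur = cell_currents(st, p, g_na_scale);
  const double V = st[iV];
  const double itot = cur.total() + i_stim;

  // gating (Rush-Larsen)
  {
    const double CaSS = st[iCaSS];
    const double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
    const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    const double taum = am * bm;
    const double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    const double tauh = 1.0 / (ah + bh);
    const double tauj = 1.0 / (aj + bj);
    const double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    const double taud = ad * bd + gd;
    const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    const double tauf = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                        200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                        180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    const double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    const double tauf2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                         31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                         80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    const double cs = (CaSS / 0.05) * (CaSS / 0.05);
    const double fcassinf = 0.6 / (1.0 + cs) + 0.4;
    const double taufcass = 80.0 / (1.0 + cs) + 2.0;
    const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    const double taur = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    const double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    const double taus = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                        5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    const double tauxs = axs * bxs + 80.0;
    st[im] = rl_update(st[im], minf, taum, dt);
    st[ih] = rl_update(st[ih], hinf, tauh, dt);
    st[ij] = rl_update(st[ij], hinf, tauj, dt);
    st[id] = rl_update(st[id], dinf, taud, dt);
    st[if_] = rl_update(st[if_], finf, tauf, dt);
    st[if2] = rl_update(st[if2], f2inf, tauf2, dt);
    st[ifcass] = rl_update(st[ifcass], fcassinf, taufcass, dt);
    st[ir] = rl_update(st[ir], rinf, taur, dt);
    st[is_] = rl_update(st[is_], sinf, taus, dt);
    st[ixr1] = rl_update(st[ixr1], xr1inf, axr1 * bxr1, dt);
    st[ixr2] = rl_update(st[ixr2], xr2inf, axr2 * bxr2, dt);
    st[ixs] = rl_update(st[ixs], xsinf, tauxs, dt);
  }

  const double cm_vc_f = p.Cm / (p.V_c * p.Faraday);
  const double cm_2vcf = p.Cm / (2.0 * p.V_c * p.Faraday);
  const double cm_2vssf = p.Cm / (2.0 * p.V_ss * p.Faraday);
  const double Ileak = p.V_leak * (st[iCaSR] - st[iCai]);
  const double Iup =
      p.V_max_pump / (1.0 + (p.K_up / st[iCai]) * (p.K_up / st[iCai]));
  const double Ixfer = p.V_xfer * (st[iCaSS] - st[iCai]);
  const double d_casr = dt * (Iup - j_rel - Ileak);
  st[iCaSR] = buffer_root(st[iCaSR], p.Buf_sr, p.K_buf_sr, d_casr);
  const double d_cass =
      dt * (-Ixfer * p.V_c / p.V_ss + j_rel * p.V_sr / p.V_ss -
            cur.ICaL * cm_2vssf);
  st[iCaSS] = buffer_root(st[iCaSS], p.Buf_ss, p.K_buf_ss, d_cass);
  const double d_cai =
      dt * (-(cur.IbCa + cur.IpCa - 2.0 * cur.INaCa) * cm_2vcf -
            (Iup - Ileak) * p.V_sr / p.V_c + Ixfer);
  st[iCai] = buffer_root(st[iCai], p.Buf_c, p.K_buf_c, d_cai);
  st[iNai] -= dt * (cur.INa + cur.IbNa + 3.0 * cur.INaK + 3.0 * cur.INaCa) *
              cm_vc_f;
  st[iKi] -= dt * (i_stim + cur.IK1 + cur.Ito + cur.IKr + cur.IKs -
                   2.0 * cur.INaK + cur.IpK) * cm_vc_f;
  st[iV] = V - dt * itot;
  return cur;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List grid, List release, List membrane, List channels,
                NumericVector state0, List protocol, List numerics,
                double seed) {
  // grid / field constants
  const int nx = as<int>(grid["nx"]), ny = as<int>(grid["ny"]);
  const double h = getp(grid, "h");
  const double Dx = getp(grid, "D_x"), Dy = getp(grid, "D_y"),
               Ddye = getp(grid, "D_dye");
  const double dye_tot = getp(grid, "dye_total"),
               dye_kon = getp(grid, "dye_kon"),
               dye_koff = getp(grid, "dye_koff");
  const double buf_tot = getp(grid, "buf_total"),
               buf_kon = getp(grid, "buf_kon"),
               buf_koff = getp(grid, "buf_koff");
  const double pump_vmax = getp(grid, "pump_vmax"),
               pump_km = getp(grid, "pump_km");
  const int pump_hill = as<int>(grid["pump_hill"]);
  const double leak = getp(grid, "leak");
  const double conv = getp(grid, "conv");  // pmol/ms -> mM/ms at one voxel
  const double ca0 = getp(grid, "ca0");

  // release constants
  const double v_cluster = getp(release, "V_cluster"),
               j_rogue = getp(release, "J_rogue_amp"),
               p_max = getp(release, "P_max"),
               km_cl = getp(release, "K_m_cluster"),
               km_ro = getp(release, "K_m_rogue"),
               n_cl = getp(release, "n_cluster"),
               n_ro = getp(release, "n_rogue"),
               k_max = getp(release, "k_max"),
               d_sr = getp(release, "D_SR"), n_sr = getp(release, "n_SR"),
               k_rel = getp(release, "k_rel"),
               t_open_cl = getp(release, "t_open_cluster"),
               t_open_ro = getp(release, "t_open_rogue"),
               t_refr = getp(release, "t_refractory"),
               gamma_dyad = getp(release, "gamma_dyad");

  const CellPars cp = read_cell_pars(membrane);

  // channels: 0-based linear node indices, cluster footprints as CSR
  const IntegerVector cl_node = channels["cluster_node"];
  const IntegerVector ro_node = channels["rogue_node"];
  const IntegerVector fp_off = channels["fp_off"];
  const IntegerVector fp_idx = channels["fp_idx"];
  const NumericVector fp_w = channels["fp_w"];
  const int ncl = cl_node.size(), nro = ro_node.size();

  // optional deterministic forcing: channel held open during [on, off)
  const IntegerVector force_kind = channels["force_kind"];  // 0 cl, 1 rogue
  const IntegerVector force_idx = channels["force_idx"];    // 0-based
  const NumericVector force_on = channels["force_on"];
  const NumericVector force_off = channels["force_off"];
  std::vector<int> cl_forced(ncl, -1), ro_forced(nro, -1);
  for (int k = 0; k < force_kind.size(); ++k) {
    if (force_kind[k] == 0) cl_forced[force_idx[k]] = k;
    else ro_forced[force_idx[k]] = k;
  }

  // protocol
  const NumericVector stim_start = protocol["stim_start"];
  const double stim_dur = getp(protocol, "stim_dur"),
               stim_amp = getp(protocol, "stim_amp"),
               t_end = getp(protocol, "t_end"),
               gna_zero_after = getp(protocol, "gna_zero_after");

  // numerics
  const double dt = getp(numerics, "dt");
  const int gating_every = as<int>(numerics["gating_every"]);
  const int rec_every = as<int>(numerics["rec_every"]);
  const int linescan_row = as<int>(numerics["linescan_row"]);  // 0-based iy
  const bool stochastic = as<bool>(numerics["stochastic"]);

  const long n_steps = (long)std::llround(t_end / dt);
  const int n_samp = (int)(n_steps / rec_every) + 1;
  const int nn = nx * ny;
  const double dx2 = Dx / (h * h), dy2 = Dy / (h * h), ddye2 = Ddye / (h * h);

  // field state
  std::vector<double> ca(nn, ca0), db(nn), bb(nn);
  const double kd_dye = dye_koff / dye_kon, kd_buf = buf_koff / buf_kon;
  std::fill(db.begin(), db.end(), dye_tot * ca0 / (ca0 + kd_dye));
  std::fill(bb.begin(), bb.end(), buf_tot * ca0 / (ca0 + kd_buf));
  std::vector<double> ca_new(nn), db_new(nn), src(nn, 0.0);

  // channel state: 0 closed, 1 open, 2 refractory
  std::vector<int> cl_state(ncl, 0), ro_state(nro, 0);
  std::vector<double> cl_timer(ncl, 0.0), ro_timer(nro, 0.0);
  std::vector<int> open_cl, open_ro;
  open_cl.reserve(ncl); open_ro.reserve(nro);

  // cell state
  double st[NSTATE];
  for (int k = 0; k < NSTATE; ++k) st[k] = state0[k];

  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  const int NCOL = 11;
  NumericMatrix series(n_samp, NCOL);
  NumericMatrix linescan(nx, n_samp);
  long n_open_events_cl = 0, n_open_events_ro = 0;
  double icalprev = 0.0;
  const double dt_g = gating_every * dt;
  const double pacing_end =
      stim_start.size() > 0 ? stim_start[stim_start.size() - 1] + stim_dur
                            : 0.0;
  int isamp = 0;
  double j_rel_rec = 0.0;

  for (long s = 0; s <= n_steps; ++s) {
    const double t = s * dt;

    // --- gating update -----------------------------------------------------
    if (s % gating_every == 0) {
      const double casr = st[iCaSR];
      const double kcasr =
          k_max / (1.0 + std::pow(d_sr / std::max(casr, 1e-9), n_sr));
      const double dyad = gamma_dyad * std::max(0.0, -icalprev);
      open_cl.clear(); open_ro.clear();
      // clusters (row-major order), then rogues
      for (int k = 0; k < ncl; ++k) {
        if (cl_forced[k] >= 0) {
          const int fidx = cl_forced[k];
          cl_state[k] =
              (t >= force_on[fidx] && t < force_off[fidx]) ? 1 : 0;
          if (cl_state[k] == 1) open_cl.push_back(k);
          continue;
        }
        if (cl_state[k] != 0) {
          cl_timer[k] -= dt_g;
          if (cl_state[k] == 1 && cl_timer[k] <= 0) {
            cl_state[k] = 2; cl_timer[k] = t_refr;
          } else if (cl_state[k] == 2 && cl_timer[k] <= 0) {
            cl_state[k] = 0; cl_timer[k] = 0;
          }
        }
        if (cl_state[k] == 0 && stochastic) {
          const double ca_loc = std::max(ca[cl_node[k]] + dyad, 1e-12);
          const double pj =
              p_max / (1.0 + std::pow(km_cl / ca_loc, n_cl)) * kcasr;
          if (pj * dt_g > 1.0)
            stop("engine: P_j * dt > 1 for a cluster; use a smaller gating interval");
          if (rng.unif() < pj * dt_g) {
            cl_state[k] = 1; cl_timer[k] = t_open_cl;
            ++n_open_events_cl;
          }
        }
        if (cl_state[k] == 1) open_cl.push_back(k);
      }
      for (int k = 0; k < nro; ++k) {
        if (ro_forced[k] >= 0) {
          const int fidx = ro_forced[k];
          ro_state[k] =
              (t >= force_on[fidx] && t < force_off[fidx]) ? 1 : 0;
          if (ro_state[k] == 1) open_ro.push_back(k);
          continue;
        }
        if (ro_state[k] != 0) {
          ro_timer[k] -= dt_g;
          if (ro_state[k] == 1 && ro_timer[k] <= 0) {
            ro_state[k] = 2; ro_timer[k] = t_refr;
          } else if (ro_state[k] == 2 && ro_timer[k] <= 0) {
            ro_state[k] = 0; ro_timer[k] = 0;
          }
        }
        if (ro_state[k] == 0 && stochastic) {
          const double ca_loc = std::max(ca[ro_node[k]], 1e-12);
          const double pj =
              p_max / (1.0 + std::pow(km_ro / ca_loc, n_ro)) * kcasr;
          if (pj * dt_g > 1.0)
            stop("engine: P_j * dt > 1 for a rogue channel; use a smaller gating interval");
          if (rng.unif() < pj * dt_g) {
            ro_state[k] = 1; ro_timer[k] = t_open_ro;
            ++n_open_events_ro;
          }
        }
        if (ro_state[k] == 1) open_ro.push_back(k);
      }
    }

    // --- release sources ---------------------------------------------------
    std::fill(src.begin(), src.end(), 0.0);
    double j_total = 0.0;  // pmol/ms
    const double casr = st[iCaSR];
    for (size_t q = 0; q < open_cl.size(); ++q) {
      const int k = open_cl[q];
      const double jc =
          std::max(0.0, v_cluster * (casr - ca[cl_node[k]]));
      j_total += jc;
      for (int m = fp_off[k]; m < fp_off[k + 1]; ++m)
        src[fp_idx[m]] += jc * fp_w[m] * conv;
    }
    for (size_t q = 0; q < open_ro.size(); ++q) {
      const int k = open_ro[q];
      j_total += j_rogue;
      src[ro_node[k]] += j_rogue * conv;
    }
    const double j_sub = j_total / cp.V_c;  // cytosolic mM/ms
    const double j_rel = k_rel * j_sub;
    j_rel_rec = j_rel;

    // --- record (state at time t, before stepping) -------------------------
    if (s % rec_every == 0 && isamp < n_samp) {
      const double gns =
          (R_finite(gna_zero_after) && t >= gna_zero_after) ? 0.0 : 1.0;
      const Currents cur = cell_currents(st, cp, gns);
      double ca_sum = 0.0;
      for (int k = 0; k < nn; ++k) ca_sum += ca[k];
      series(isamp, 0) = t;
      series(isamp, 1) = st[iV];
      series(isamp, 2) = st[iCai];
      series(isamp, 3) = st[iCaSR];
      series(isamp, 4) = st[iCaSS];
      series(isamp, 5) = cur.INaCa;
      series(isamp, 6) = cur.ICaL;
      series(isamp, 7) = j_rel;
      series(isamp, 8) = ca_sum / nn;
      series(isamp, 9) = (double)open_cl.size();
      series(isamp, 10) = (double)open_ro.size();
      for (int i = 0; i < nx; ++i)
        linescan(i, isamp) = ca[(size_t)linescan_row * nx + i];
      ++isamp;
    }
    if (s == n_steps) break;

    // --- field step (zero-flux boundaries, reflected neighbours) -----------
    for (int jy = 0; jy < ny; ++jy) {
      const int jm = (jy == 0) ? 0 : jy - 1;
      const int jp = (jy == ny - 1) ? ny - 1 : jy + 1;
      const double* row = &ca[(size_t)jy * nx];
      const double* rym = &ca[(size_t)jm * nx];
      const double* ryp = &ca[(size_t)jp * nx];
      const double* drow = &db[(size_t)jy * nx];
      const double* dym = &db[(size_t)jm * nx];
      const double* dyp = &db[(size_t)jp * nx];
      const double* brow = &bb[(size_t)jy * nx];
      const double* srow = &src[(size_t)jy * nx];
      double* out_ca = &ca_new[(size_t)jy * nx];
      double* out_db = &db_new[(size_t)jy * nx];
      double* out_bb = &bb[(size_t)jy * nx];
      for (int i = 0; i < nx; ++i) {
        const int imn = (i == 0) ? 0 : i - 1;
        const int ipn = (i == nx - 1) ? nx - 1 : i + 1;
        const double c = row[i];
        const double lap = dx2 * (row[imn] + row[ipn] - 2.0 * c) +
                           dy2 * (rym[i] + ryp[i] - 2.0 * c);
        const double dcur = drow[i];
        const double lapd = ddye2 * (drow[imn] + drow[ipn] - 2.0 * dcur) +
                            ddye2 * (dym[i] + dyp[i] - 2.0 * dcur);
        const double r_dye = dye_kon * c * (dye_tot - dcur) - dye_koff * dcur;
        const double bcur = brow[i];
        const double r_buf = buf_kon * c * (buf_tot - bcur) - buf_koff * bcur;
        double cn = c;
        // integer Hill exponent for the field pump
        double cpow = c, kpow = pump_km;
        for (int e = 1; e < pump_hill; ++e) { cpow *= c; kpow *= pump_km; }
        const double pump = pump_vmax * cpow / (cpow + kpow);
        cn += dt * (lap - r_dye - r_buf - pump + leak + srow[i]);
        out_ca[i] = cn > 0.0 ? cn : 0.0;
        const double dn = dcur + dt * (lapd + r_dye);
        out_db[i] = dn > 0.0 ? dn : 0.0;
        const double bn = bcur + dt * r_buf;
        out_bb[i] = bn > 0.0 ? bn : 0.0;
      }
    }
    ca.swap(ca_new);
    db.swap(db_new);

    // --- cell step ----------------------------------------------------------
    double i_stim = 0.0;
    for (int k = 0; k < stim_start.size(); ++k)
      if (t >= stim_start[k] && t < stim_start[k] + stim_dur) {
        i_stim = -stim_amp;
        break;
      }
    const double gns =
        (R_finite(gna_zero_after) && t >= gna_zero_after) ? 0.0 : 1.0;
    const Currents cur = step_cell_cpp(st, j_rel, i_stim, cp, dt, gns);
    icalprev = cur.ICaL;
    if (!std::isfinite(st[iV]) || st[iV] < -120.0 || st[iV] > 80.0)
      stop("engine: numerical failure at t = %.2f ms (V = %.2f mV)", t,
           st[iV]);
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  (void)pacing_end;

  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = st[k];
  NumericMatrix ca_final(nx, ny);
  for (int jy = 0; jy < ny; ++jy)
    for (int i = 0; i < nx; ++i) ca_final(i, jy) = ca[(size_t)jy * nx + i];

  return List::create(
      _["series"] = series, _["linescan"] = linescan,
      _["final_state"] = fin, _["ca_final"] = ca_final,
      _["n_cluster_openings"] = (double)n_open_events_cl,
      _["n_rogue_openings"] = (double)n_open_events_ro,
      _["j_rel_last"] = j_rel_rec);
}
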
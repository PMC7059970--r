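// Fixed-step RK4 integrator for the striatal FSI/SPN microcircuit.
//
// State layout (length L):
//   [0, nf)                FSI soma V
//   [nf, 5 nf)             FSI soma h, n, a, b
//   [5 nf, 6 nf)           FSI dend V
//   [6 nf, 10 nf)          FSI dend h, n, a, b
//   [10 nf, 10 nf + ns)    SPN V
//   ... + ns*4             SPN m, h, n, w
//   ... + nf               GABA gate per FSI source
//   ... + ns               GABA gate per SPN source
//
// One gate per presynaptic cell: every directed GABA-A synapse from cell k
// shares the same gate ODE (driven only by V_k) and initial condition, so the
// per-synapse gates of the formal model are identical copies and the
// postsynaptic drive is an adjacency-weighted sum of per-source gates.
//
// Noise (Poisson events on FSI dendrites, Gaussian current on SPNs) is held
// constant across the four RK4 stages of a step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

struct CSC {  // per-postsynaptic-target source lists
  std::vector<int> ptr;   // size ncol+1
  std::vector<int> src;   // row indices
};

CSC build_csc(const IntegerMatrix &m) {
  CSC a;
  int nr = m.nrow(), nc = m.ncol();
  a.ptr.assign(nc + 1, 0);
  for (int j = 0; j < nc; ++j) {
    int cnt = 0;
    for (int i = 0; i < nr; ++i) if (m(i, j)) ++cnt;
    a.ptr[j + 1] = a.ptr[j] + cnt;
  }
  a.src.resize(a.ptr[nc]);
  for (int j = 0, k = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) if (m(i, j)) a.src[k++] = i;
  return a;
}

bool is_all_to_all(const IntegerMatrix &m) {
  int n = m.nrow();
  if (m.ncol() != n) return false;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (m(i, j) != (i == j ? 0 : 1)) return false;
  return true;
}

struct FsiPar {
  double c_m, g_Na, g_K, E_Na, E_K, E_L, tau_a, tau_b, dscale, gcomp;
  std::vector<double> g_L, g_D, I_app;  // per cell
};

struct SpnPar {
  double c_m, g_Na, g_K, g_L, g_M, E_Na, E_K, E_L, Qs;
  std::vector<double> I_app;  // per cell
};

struct SynPar {
  double g_ff, g_fs, g_ss, tau_i, tau_r, E_i, g_gj;
};

// x / (1 - exp(-x/s)) with limit s at x = 0
inline double rate_linexp(double x, double s) {
  if (std::fabs(x) < 1e-6) return s;
  return x / -std::expm1(-x / s);
}

struct Net {
  int nf, n1, n2, ns, L;
  FsiPar fsi;
  SpnPar spn;
  SynPar syn;
  CSC ff, f1, f2, gj, d11, d22;
  bool d11_a2a, d22_a2a;
  // offsets
  int o_vs, o_hs, o_ns_, o_as, o_bs, o_vd, o_hd, o_nd, o_ad, o_bd;
  int o_vspn, o_m, o_h, o_n, o_w, o_Sf, o_Ss;

  void offsets() {
    int nf_ = nf;
    o_vs = 0; o_hs = nf_; o_ns_ = 2 * nf_; o_as = 3 * nf_; o_bs = 4 * nf_;
    o_vd = 5 * nf_; o_hd = 6 * nf_; o_nd = 7 * nf_; o_ad = 8 * nf_; o_bd = 9 * nf_;
    o_vspn = 10 * nf_;
    o_m = o_vspn + ns; o_h = o_m + ns; o_n = o_h + ns; o_w = o_n + ns;
    o_Sf = o_w + ns; o_Ss = o_Sf + nf_;
    L = o_Ss + ns;
  }

  // drive: per-FSI dendritic external current (tonic + noise + pulse),
  // spn_drive: per-SPN applied current (tonic + noise + pulse)
  void rhs(const double *y, double *dy,
           const double *fsi_drive, const double *spn_drive) const {
    // synaptic gate sums per postsynaptic cell
    std::vector<double> sum_ff(nf, 0.0), sum_fs(ns, 0.0), sum_ss(ns, 0.0);
    const double *Sf = y + o_Sf, *Ss = y + o_Ss;
    for (int j = 0; j < nf; ++j) {
      double s = 0.0;
      for (int k = ff.ptr[j]; k < ff.ptr[j + 1]; ++k) s += Sf[ff.src[k]];
      sum_ff[j] = s;
    }
    for (int j = 0; j < n1; ++j) {
      double s = 0.0;
      for (int k = f1.ptr[j]; k < f1.ptr[j + 1]; ++k) s += Sf[f1.src[k]];
      sum_fs[j] = s;
    }
    for (int j = 0; j < n2; ++j) {
      double s = 0.0;
      for (int k = f2.ptr[j]; k < f2.ptr[j + 1]; ++k) s += Sf[f2.src[k]];
      sum_fs[n1 + j] = s;
    }
    if (d11_a2a) {
      double tot = 0.0;
      for (int k = 0; k < n1; ++k) tot += Ss[k];
      for (int j = 0; j < n1; ++j) sum_ss[j] = tot - Ss[j];
    } else {
      for (int j = 0; j < n1; ++j) {
        double s = 0.0;
        for (int k = d11.ptr[j]; k < d11.ptr[j + 1]; ++k) s += Ss[d11.src[k]];
        sum_ss[j] = s;
      }
    }
    if (d22_a2a) {
      double tot = 0.0;
      for (int k = 0; k < n2; ++k) tot += Ss[n1 + k];
      for (int j = 0; j < n2; ++j) sum_ss[n1 + j] = tot - Ss[n1 + j];
    } else {
      for (int j = 0; j < n2; ++j) {
        double s = 0.0;
        for (int k = d22.ptr[j]; k < d22.ptr[j + 1]; ++k) s += Ss[n1 + d22.src[k]];
        sum_ss[n1 + j] = s;
      }
    }

    // FSI compartments
    for (int i = 0; i < nf; ++i) {
      double Vs = y[o_vs + i], Vd = y[o_vd + i];
      // gap junction current into dendrite i
      double Igj = 0.0;
      for (int k = gj.ptr[i]; k < gj.ptr[i + 1]; ++k)
        Igj += y[o_vd + gj.src[k]] - Vd;
      Igj *= syn.g_gj;
      double Isyn_soma = syn.g_ff * sum_ff[i] * (Vs - syn.E_i);
      double Ids = fsi.gcomp * (Vd - Vs);  // into soma
      double Isd = fsi.gcomp * (Vs - Vd);  // into dendrite

      for (int c = 0; c < 2; ++c) {
        bool soma = (c == 0);
        double V = soma ? Vs : Vd;
        double scale = soma ? 1.0 : fsi.dscale;
        double h = y[(soma ? o_hs : o_hd) + i];
        double n = y[(soma ? o_ns_ : o_nd) + i];
        double a = y[(soma ? o_as : o_ad) + i];
        double b = y[(soma ? o_bs : o_bd) + i];
        double m_inf = 1.0 / (1.0 + std::exp(-(V + 24.0) / 11.5));
        double h_inf = 1.0 / (1.0 + std::exp((V + 58.3) / 6.7));
        double tau_h = 0.5 + 14.0 / (1.0 + std::exp((V + 60.0) / 12.0));
        double n_inf = 1.0 / (1.0 + std::exp(-(V + 12.4) / 6.8));
        double tau_n = (0.087 + 11.4 / (1.0 + std::exp((V + 14.6) / 8.6))) *
                       (0.087 + 11.4 / (1.0 + std::exp(-(V - 1.3) / 18.7)));
        double a_inf = 1.0 / (1.0 + std::exp(-(V + 50.0) / 20.0));
        double b_inf = 1.0 / (1.0 + std::exp((V + 70.0) / 6.0));
        double INa = scale * fsi.g_Na * m_inf * m_inf * m_inf * h * (V - fsi.E_Na);
        double IK  = scale * fsi.g_K * n * n * (V - fsi.E_K);
        double IL  = scale * fsi.g_L[i] * (V - fsi.E_L);
        double ID  = scale * fsi.g_D[i] * a * a * a * b * (V - fsi.E_K);
        double Iextra = soma ? (-Isyn_soma + Ids)
                             : (fsi_drive[i] + Igj + Isd);
        dy[(soma ? o_vs : o_vd) + i] = (-INa - IK - IL - ID + Iextra) / fsi.c_m;
        dy[(soma ? o_hs : o_hd) + i] = (h_inf - h) / tau_h;
        dy[(soma ? o_ns_ : o_nd) + i] = (n_inf - n) / tau_n;
        dy[(soma ? o_as : o_ad) + i] = (a_inf - a) / fsi.tau_a;
        dy[(soma ? o_bs : o_bd) + i] = (b_inf - b) / fsi.tau_b;
      }
      // FSI source gate
      double S = Sf[i];
      double open = (1.0 / syn.tau_r) * (1.0 + std::tanh(Vs / 10.0));
      dy[o_Sf + i] = open * (1.0 - S) - S / syn.tau_i;
    }

    // SPNs
    for (int j = 0; j < ns; ++j) {
      double V = y[o_vspn + j];
      double m = y[o_m + j], h = y[o_h + j], n = y[o_n + j], w = y[o_w + j];
      double am = 0.32 * rate_linexp(V + 54.0, 4.0);
      double bm = 0.28 * rate_linexp(-(V + 27.0), 5.0);
      double ah = 0.128 * std::exp(-(V + 50.0) / 18.0);
      double bh = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
      double an = 0.032 * rate_linexp(V + 52.0, 5.0);
      double bn = 0.5 * std::exp(-(V + 57.0) / 40.0);
      double aw = spn.Qs * 1e-4 * rate_linexp(V + 30.0, 9.0);
      double bw = spn.Qs * 1e-4 * rate_linexp(-(V + 30.0), 9.0);
      double INa = spn.g_Na * m * m * m * h * (V - spn.E_Na);
      double IK  = spn.g_K * n * n * n * n * (V - spn.E_K);
      double IL  = spn.g_L * (V - spn.E_L);
      double IM  = spn.g_M * w * (V - spn.E_K);
      double Isyn = (syn.g_fs * sum_fs[j] + syn.g_ss * sum_ss[j]) * (V - syn.E_i);
      dy[o_vspn + j] = (-INa - IK - IL - IM - Isyn + spn_drive[j]) / spn.c_m;
      dy[o_m + j] = am * (1.0 - m) - bm * m;
      dy[o_h + j] = ah * (1.0 - h) - bh * h;
      dy[o_n + j] = an * (1.0 - n) - bn * n;
      dy[o_w + j] = aw * (1.0 - w) - bw * w;
      // SPN source gate
      double S = Ss[j];
      double open = 2.0 * (1.0 + std::tanh(V / 4.0));
      dy[o_Ss + j] = open * (1.0 - S) - S / syn.tau_i;
    }
  }
};

Net net_from_config(const List &cfg) {
  Net N;
  N.nf = as<int>(cfg["n_fsi"]);
  N.n1 = as<int>(cfg["n_d1"]);
  N.n2 = as<int>(cfg["n_d2"]);
  N.ns = N.n1 + N.n2;
  List fp = cfg["fsi"];
  N.fsi.c_m = as<double>(fp["c_m"]);
  N.fsi.g_Na = as<double>(fp["g_Na"]);
  N.fsi.g_K = as<double>(fp["g_K"]);
  N.fsi.E_Na = as<double>(fp["E_Na"]);
  N.fsi.E_K = as<double>(fp["E_K"]);
  N.fsi.E_L = as<double>(fp["E_L"]);
  N.fsi.tau_a = as<double>(fp["tau_a"]);
  N.fsi.tau_b = as<double>(fp["tau_b"]);
  N.fsi.dscale = as<double>(fp["dendrite_scale"]);
  N.fsi.gcomp = as<double>(fp["g_compartment"]);
  N.fsi.g_L = as<std::vector<double>>(fp["g_L_cell"]);
  N.fsi.g_D = as<std::vector<double>>(fp["g_D_cell"]);
  N.fsi.I_app = as<std::vector<double>>(fp["I_app_cell"]);
  List sp = cfg["spn"];
  N.spn.c_m = as<double>(sp["c_m"]);
  N.spn.g_Na = as<double>(sp["g_Na"]);
  N.spn.g_K = as<double>(sp["g_K"]);
  N.spn.g_L = as<double>(sp["g_L"]);
  N.spn.g_M = as<double>(sp["g_M"]);
  N.spn.E_Na = as<double>(sp["E_Na"]);
  N.spn.E_K = as<double>(sp["E_K"]);
  N.spn.E_L = as<double>(sp["E_L"]);
  N.spn.Qs = as<double>(sp["Qs"]);
  N.spn.I_app = as<std::vector<double>>(sp["I_app_cell"]);
  List sy = cfg["syn"];
  N.syn.g_ff = as<double>(sy["g_fsi_fsi"]);
  N.syn.g_fs = as<double>(sy["g_fsi_spn"]);
  N.syn.g_ss = as<double>(sy["g_spn_spn"]);
  N.syn.tau_i = as<double>(sy["tau_i"]);
  N.syn.tau_r = as<double>(sy["tau_r"]);
  N.syn.E_i = as<double>(sy["E_i"]);
  N.syn.g_gj = as<double>(sy["g_gj"]);
  List cn = cfg["conn"];
  IntegerMatrix gj = cn["gj"], ff = cn["fsi_inh"], f1 = cn["fsi_d1"],
                f2 = cn["fsi_d2"], d11 = cn["d1_d1"], d22 = cn["d2_d2"];
  N.gj = build_csc(gj);   // symmetric: per-column lists serve as per-row
  N.ff = build_csc(ff);
  N.f1 = build_csc(f1);
  N.f2 = build_csc(f2);
  N.d11_a2a = is_all_to_all(d11);
  N.d22_a2a = is_all_to_all(d22);
  if (!N.d11_a2a) N.d11 = build_csc(d11);
  if (!N.d22_a2a) N.d22 = build_csc(d22);
  N.offsets();
  return N;
}

std::string state_name(const Net &N, int idx) {
  if (idx < N.o_vspn) {
    int block = idx / N.nf, cell = idx % N.nf;
    const char *names[] = {"V_soma", "h_s", "n_s", "a_s", "b_s",
                           "V_dend", "h_d", "n_d", "a_d", "b_d"};
    return std::string("fsi[") + std::to_string(cell + 1) + "]." + names[block];
  }
  if (idx < N.o_Sf) {
    int rel = idx - N.o_vspn, block = rel / N.ns, cell = rel % N.ns;
    const char *names[] = {"V", "m", "h", "n", "w"};
    return std::string("spn[") + std::to_string(cell + 1) + "]." + names[block];
  }
  if (idx < N.o_Ss) return "S_fsi[" + std::to_string(idx - N.o_Sf + 1) + "]";
  return "S_spn[" + std::to_string(idx - N.o_Ss + 1) + "]";
}

inline bool is_gate(const Net &N, int idx) {
  if (idx >= N.o_Sf) return true;                         // synaptic gates
  if (idx < N.o_vspn) {                                   // FSI blocks
    int block = idx / N.nf;
    return block != 0 && block != 5;                      // not V_soma/V_dend
  }
  return idx >= N.o_m;                                    // SPN gates
}

}  // namespace

// [[Rcpp::export]]
List engine_simulate(List cfg, NumericVector y0, List integ, List noise,
                     NumericMatrix pulses, List detect) {
  Net N = net_from_config(cfg);
  if ((int)y0.size() != N.L) stop("state vector length %d, expected %d",
                                  (int)y0.size(), N.L);
  double dt = as<double>(integ["dt"]);
  int n_steps = as<int>(integ["n_steps"]);
  int stride = as<int>(integ["record_stride"]);
  bool record_gates = as<bool>(integ["record_gates"]);

  bool noise_on = as<bool>(noise["on"]);
  double p_rate = as<double>(noise["fsi_poisson_rate"]);      // events/ms
  double p_amp = as<double>(noise["fsi_poisson_amplitude"]);  // uA/cm^2
  int p_kernel = as<int>(noise["fsi_poisson_kernel"]);        // 0 rect, 1 exp
  double p_tau = as<double>(noise["fsi_poisson_tau"]);        // ms (exp kernel)
  double g_sd = as<double>(noise["spn_noise_sd"]);            // uA/cm^2, resolved

  double thr = as<double>(detect["threshold"]);
  double refrac = as<double>(detect["refractory"]);

  double p_event = p_rate * dt;  // Bernoulli event probability per step
  double p_decay = (p_kernel == 1) ? std::exp(-dt / p_tau) : 0.0;

  int n_rec = n_steps / stride + 1;
  NumericVector time(n_rec);
  NumericMatrix v_fsi_soma(n_rec, N.nf), v_fsi_dend(n_rec, N.nf),
      v_spn(n_rec, N.ns), i_gaba(n_rec, N.nf + N.ns), i_gj(n_rec, N.nf);
  NumericMatrix states;
  if (record_gates) states = NumericMatrix(n_rec, N.L);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(N.L), k2(N.L), k3(N.L), k4(N.L), yt(N.L);
  std::vector<double> fsi_drive(N.nf, 0.0), spn_drive(N.ns, 0.0);
  std::vector<double> p_state(N.nf, 0.0);  // kernel state of Poisson drive

  // spike detection bookkeeping (soma V for FSIs)
  int n_cells = N.nf + N.ns;
  std::vector<double> last_spike(n_cells, -1e18), prev_v(n_cells);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  double gate_min = 1.0, gate_max = 0.0;

  RNGScope rng;

  auto record = [&](int r, double t) {
    time[r] = t;
    // recompute synaptic sums for current recording
    std::vector<double> dtmp(N.L);
    // cheap: reuse rhs path only for sums? recompute sums directly
    const double *Sf = y.data() + N.o_Sf, *Ss = y.data() + N.o_Ss;
    for (int i = 0; i < N.nf; ++i) {
      v_fsi_soma(r, i) = y[N.o_vs + i];
      v_fsi_dend(r, i) = y[N.o_vd + i];
      double s = 0.0;
      for (int k = N.ff.ptr[i]; k < N.ff.ptr[i + 1]; ++k) s += Sf[N.ff.src[k]];
      i_gaba(r, i) = N.syn.g_ff * s * (y[N.o_vs + i] - N.syn.E_i);
      double gsum = 0.0;
      for (int k = N.gj.ptr[i]; k < N.gj.ptr[i + 1]; ++k)
        gsum += y[N.o_vd + N.gj.src[k]] - y[N.o_vd + i];
      i_gj(r, i) = N.syn.g_gj * gsum;
    }
    double tot1 = 0.0, tot2 = 0.0;
    for (int k = 0; k < N.n1; ++k) tot1 += Ss[k];
    for (int k = 0; k < N.n2; ++k) tot2 += Ss[N.n1 + k];
    for (int j = 0; j < N.ns; ++j) {
      double V = y[N.o_vspn + j];
      v_spn(r, j) = V;
      double sfs = 0.0;
      if (j < N.n1) {
        for (int k = N.f1.ptr[j]; k < N.f1.ptr[j + 1]; ++k) sfs += Sf[N.f1.src[k]];
      } else {
        int jj = j - N.n1;
        for (int k = N.f2.ptr[jj]; k < N.f2.ptr[jj + 1]; ++k) sfs += Sf[N.f2.src[k]];
      }
      double sss;
      if (j < N.n1) {
        if (N.d11_a2a) sss = tot1 - Ss[j];
        else { sss = 0; for (int k = N.d11.ptr[j]; k < N.d11.ptr[j + 1]; ++k) sss += Ss[N.d11.src[k]]; }
      } else {
        int jj = j - N.n1;
        if (N.d22_a2a) sss = tot2 - Ss[N.n1 + jj];
        else { sss = 0; for (int k = N.d22.ptr[jj]; k < N.d22.ptr[jj + 1]; ++k) sss += Ss[N.n1 + N.d22.src[k]]; }
      }
      i_gaba(r, N.nf + j) = (N.syn.g_fs * sfs + N.syn.g_ss * sss) * (V - N.syn.E_i);
    }
    if (record_gates) for (int k = 0; k < N.L; ++k) states(r, k) = y[k];
  };

  for (int i = 0; i < N.nf; ++i) prev_v[i] = y[N.o_vs + i];
  for (int j = 0; j < N.ns; ++j) prev_v[N.nf + j] = y[N.o_vspn + j];
  record(0, 0.0);
  int rec_row = 1;

  int n_pulse = pulses.nrow();

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // drives for this step
    for (int i = 0; i < N.nf; ++i) {
      double drive = N.fsi.I_app[i];
      if (noise_on && p_rate > 0) {
        bool event = unif_rand() < p_event;
        if (p_kernel == 1) {
          p_state[i] *= p_decay;
          if (event) p_state[i] += p_amp;
        } else {
          p_state[i] = event ? p_amp : 0.0;
        }
        drive += p_state[i];
      }
      fsi_drive[i] = drive;
    }
    for (int j = 0; j < N.ns; ++j) {
      double drive = N.spn.I_app[j];
      if (noise_on && g_sd > 0) drive += g_sd * norm_rand();
      spn_drive[j] = drive;
    }
    for (int pp = 0; pp < n_pulse; ++pp) {
      if (t >= pulses(pp, 1) && t < pulses(pp, 1) + pulses(pp, 2)) {
        int cell = (int)pulses(pp, 0) - 1;  // 1-based global index
        if (cell < N.nf) fsi_drive[cell] += pulses(pp, 3);
        else spn_drive[cell - N.nf] += pulses(pp, 3);
      }
    }

    // RK4
    N.rhs(y.data(), k1.data(), fsi_drive.data(), spn_drive.data());
    for (int k = 0; k < N.L; ++k) yt[k] = y[k] + 0.5 * dt * k1[k];
    N.rhs(yt.data(), k2.data(), fsi_drive.data(), spn_drive.data());
    for (int k = 0; k < N.L; ++k) yt[k] = y[k] + 0.5 * dt * k2[k];
    N.rhs(yt.data(), k3.data(), fsi_drive.data(), spn_drive.data());
    for (int k = 0; k < N.L; ++k) yt[k] = y[k] + dt * k3[k];
    N.rhs(yt.data(), k4.data(), fsi_drive.data(), spn_drive.data());
    for (int k = 0; k < N.L; ++k)
      y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);

    double tn = t + dt;

    // gate clamp (rounding only) + bounds bookkeeping + blow-up check
    for (int k = 0; k < N.L; ++k) {
      double v = y[k];
      if (!std::isfinite(v))
        stop("non-finite state at t = %.3f ms in component %s", tn,
             state_name(N, k).c_str());
      if (is_gate(N, k)) {
        if (v < 0.0) {
          if (v < -1e-12) stop("gate underflow (%g) at t = %.3f ms in %s", v,
                               tn, state_name(N, k).c_str());
          y[k] = v = 0.0;
        } else if (v > 1.0) {
          if (v > 1.0 + 1e-12) stop("gate overflow (%g) at t = %.3f ms in %s",
                                    v, tn, state_name(N, k).c_str());
          y[k] = v = 1.0;
        }
        if (v < gate_min) gate_min = v;
        if (v > gate_max) gate_max = v;
      } else if (std::fabs(v) > 500.0) {
        stop("numerical blow-up (V = %g mV) at t = %.3f ms in %s", v, tn,
             state_name(N, k).c_str());
      }
    }

    // online spike detection (upward threshold crossing + refractory)
    for (int c = 0; c < n_cells; ++c) {
      double v = (c < N.nf) ? y[N.o_vs + c] : y[N.o_vspn + (c - N.nf)];
      if (prev_v[c] < thr && v >= thr && tn - last_spike[c] >= refrac) {
        last_spike[c] = tn;
        spike_id.push_back(c + 1);
        spike_t.push_back(tn);
      }
      prev_v[c] = v;
    }

    if ((step + 1) % stride == 0 && rec_row < n_rec) {
      record(rec_row, tn);
      ++rec_row;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["time"] = time, _["v_fsi_soma"] = v_fsi_soma,
      _["v_fsi_dend"] = v_fsi_dend, _["v_spn"] = v_spn,
      _["i_gaba"] = i_gaba, _["i_gj"] = i_gj,
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["gate_min"] = gate_min, _["gate_max"] = gate_max,
      _["final_state"] = NumericVector(y.begin(), y.end()));
  if (record_gates) out["states"] = states;
  return out;
}

// Single RHS evaluation of the full network state (for cross-checks against
// the pure-R cell and synapse right-hand sides).
// [[Rcpp::export]]
NumericVector engine_rhs(List cfg, NumericVector y, NumericVector fsi_drive,
                         NumericVector spn_drive) {
  Net N = net_from_config(cfg);
  if ((int)y.size() != N.L) stop("bad state length");
  NumericVector dy(N.L);
  N.rhs(y.begin(), dy.begin(), fsi_drive.begin(), spn_drive.begin());
  return dy;
}
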
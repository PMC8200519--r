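// Conductance-based E-I network integrator (RK4, fixed step).
//
// Cell types: 0 = reduced Traub-Miles pyramidal cell (E), 1 = Wang-Buzsaki
// basket cell (I). E cells may carry an additional non-inactivating K+
// (M-) current with a slow voltage-dependent gate. Synapses follow the
// two-variable rise/decay gating scheme: an auxiliary variable q is driven
// toward 1 by presynaptic depolarization with a 0.1 ms rise and decays with
// tau_dq (chosen in R so the gate s peaks tau_peak after a spike); s is
// charged by q with rise constant tau_r and decays with tau_d.
//
// Numerics: gating rate functions and the synaptic activation function are
// tabulated on a 0.05 mV grid (packed per-voltage rows, linear
// interpolation). Aggregate synaptic conductances are refreshed on a fixed
// 0.1 ms subgrid and held between refreshes, and the stimulus drive is
// frozen across the four RK4 substeps of a step; both vary slowly relative
// to the default dt = 0.02 ms, and step-halving convergence of the network
// rhythm is asserted in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double V_LO = -130.0, V_HI = 70.0, V_STEP = 0.05;
constexpr int NTAB = (int)((V_HI - V_LO) / V_STEP) + 2;
// packed rows: RTM: am, cm, ah, ch, an, cn, winf, twinv, open (stride 9)
//              WB : minf, ah, ch, an, cn, open            (stride 6)
constexpr int RSTR = 9, WSTR = 6;

inline double safe_exprel(double x) {
  // x / (1 - exp(-x)), guarded near 0
  if (std::fabs(x) < 1e-7) return 1.0 + x / 2.0;
  return x / (1.0 - std::exp(-x));
}

void build_tables(std::vector<double>& rtm, std::vector<double>& wb) {
  rtm.resize(NTAB * RSTR);
  wb.resize(NTAB * WSTR);
  for (int i = 0; i < NTAB; ++i) {
    double v = V_LO + i * V_STEP;
    // reduced Traub-Miles rate functions
    double am = 0.32 * 4.0 * safe_exprel((v + 54.0) / 4.0);
    double bm = 0.28 * 5.0 * safe_exprel(-(v + 27.0) / 5.0);
    double ah = 0.128 * std::exp(-(v + 50.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
    double an = 0.032 * 5.0 * safe_exprel((v + 52.0) / 5.0);
    double bn = 0.5 * std::exp(-(v + 57.0) / 40.0);
    // M-current gate (non-inactivating K+, slow)
    double winf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    double tw = 400.0 / (3.3 * std::exp((v + 35.0) / 20.0) +
                         std::exp(-(v + 35.0) / 20.0));
    double open = 0.5 * (1.0 + std::tanh(v / 10.0));
    double* r = &rtm[i * RSTR];
    r[0] = am; r[1] = am + bm; r[2] = ah; r[3] = ah + bh;
    r[4] = an; r[5] = an + bn; r[6] = winf; r[7] = 1.0 / tw; r[8] = open;
    // Wang-Buzsaki (phi = 5 on h and n; m instantaneous)
    double wam = safe_exprel((v + 35.0) / 10.0);
    double wbm = 4.0 * std::exp(-(v + 60.0) / 18.0);
    double wah = 0.35 * std::exp(-(v + 58.0) / 20.0);
    double wbh = 5.0 / (1.0 + std::exp(-0.1 * (v + 28.0)));
    double wan = 0.5 * safe_exprel((v + 34.0) / 10.0);
    double wbn = 0.625 * std::exp(-(v + 44.0) / 80.0);
    double* q = &wb[i * WSTR];
    q[0] = wam / (wam + wbm); q[1] = wah; q[2] = wah + wbh;
    q[3] = wan; q[4] = wan + wbn; q[5] = open;
  }
}

struct Deriv { double dv, dm, dh, dn, dw, dq, ds; };

} // namespace

// [[Rcpp::export]]
List sim_hh_cpp(IntegerVector type,        // 0 = RTM (E), 1 = WB (I)
                NumericVector g_M,         // per cell (mS/cm^2)
                NumericVector I0,          // static drive per cell (uA/cm^2)
                NumericVector gain1,       // stimulus-1 gain per cell
                NumericVector gain2,       // stimulus-2 gain per cell
                NumericVector stim1,       // on the integration grid
                NumericVector stim2,
                NumericMatrix Wt,          // n_post x n_pre conductances
                NumericVector tau_r, NumericVector tau_d,
                NumericVector tau_dq, NumericVector v_rev, // per presyn cell
                LogicalVector field_pool,  // cells whose synaptic input forms the field
                NumericVector v_init,
                NumericVector par_e,       // C, vNa, vK, vL, gNa, gK, gL (RTM row)
                NumericVector par_i,       // same order (WB row)
                double dt, int n_steps, int dec) {
  const int n = type.size();
  std::vector<double> rtm_tab, wb_tab;
  build_tables(rtm_tab, wb_tab);
  const double C_[2]   = {par_e[0], par_i[0]};
  const double vNa_[2] = {par_e[1], par_i[1]};
  const double vK_[2]  = {par_e[2], par_i[2]};
  const double vL_[2]  = {par_e[3], par_i[3]};
  const double gNa_[2] = {par_e[4], par_i[4]};
  const double gK_[2]  = {par_e[5], par_i[5]};
  const double gL_[2]  = {par_e[6], par_i[6]};

  std::vector<double> v(n), m(n), h(n), nn(n), w(n), q(n, 0.0), s(n, 0.0);
  auto row_at = [&](int ty, double V) -> const double* {
    double u = (V - V_LO) / V_STEP;
    if (u < 0.0) u = 0.0;
    if (u > NTAB - 2) u = NTAB - 2;
    return ty == 0 ? &rtm_tab[(int)u * RSTR] : &wb_tab[(int)u * WSTR];
  };
  for (int i = 0; i < n; ++i) {
    v[i] = v_init[i];
    const double* r = row_at(type[i], v[i]);
    if (type[i] == 0) {
      m[i] = r[0] / r[1]; h[i] = r[2] / r[3]; nn[i] = r[4] / r[5];
      w[i] = r[6];
    } else {
      m[i] = r[0]; h[i] = r[1] / r[2]; nn[i] = r[3] / r[4]; w[i] = 0.0;
    }
  }

  std::vector<double> gE(n, 0.0), gI(n, 0.0), Iext(n);
  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  std::vector<bool> above(n, false);

  const int n_out = n_steps / dec;
  std::vector<double> field(n_out, 0.0);
  const bool has_stim1 = stim1.size() > 0, has_stim2 = stim2.size() > 0;
  const int refresh = std::max(1, (int)std::lround(0.1 / dt));

  for (int step = 0; step < n_steps; ++step) {
    if (step % refresh == 0) {
      std::fill(gE.begin(), gE.end(), 0.0);
      std::fill(gI.begin(), gI.end(), 0.0);
      for (int pre = 0; pre < n; ++pre) {
        double sp = s[pre];
        if (sp < 1e-12) continue;
        const double* col = &Wt(0, pre);
        double* acc = (v_rev[pre] > -30.0) ? gE.data() : gI.data();
        for (int j = 0; j < n; ++j) acc[j] += sp * col[j];
      }
    }
    for (int i = 0; i < n; ++i) {
      double d = I0[i];
      if (has_stim1 && gain1[i] != 0.0) d += gain1[i] * stim1[step];
      if (has_stim2 && gain2[i] != 0.0) d += gain2[i] * stim2[step];
      Iext[i] = d;
    }

    double field_acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const int ty = type[i];
      const double tr_inv = 1.0 / tau_r[i], td_inv = 1.0 / tau_d[i],
                   tdq_inv = 1.0 / tau_dq[i];
      const double gEi = gE[i], gIi = gI[i], Iei = Iext[i], gMi = g_M[i];
      const double vv = v[i], mm = m[i], hh = h[i], nnn = nn[i],
                   ww = w[i], qq = q[i], ss = s[i];

      auto deriv = [&](double V, double M, double H, double N, double W2,
                       double Q, double S, Deriv& D) {
        double u = (V - V_LO) / V_STEP;
        if (u < 0.0) u = 0.0;
        if (u > NTAB - 2) u = NTAB - 2;
        int iv = (int)u;
        double fr = u - iv;
        double INa, IK, open;
        if (ty == 0) {
          const double* a = &rtm_tab[iv * RSTR];
          const double* b = a + RSTR;
          double am = a[0] + fr * (b[0] - a[0]);
          double cm = a[1] + fr * (b[1] - a[1]);
          double ah = a[2] + fr * (b[2] - a[2]);
          double ch = a[3] + fr * (b[3] - a[3]);
          double an = a[4] + fr * (b[4] - a[4]);
          double cn = a[5] + fr * (b[5] - a[5]);
          D.dm = am - cm * M; D.dh = ah - ch * H; D.dn = an - cn * N;
          INa = gNa_[0] * M * M * M * H * (vNa_[0] - V);
          double N2 = N * N;
          IK = gK_[0] * N2 * N2 * (vK_[0] - V);
          if (gMi > 0.0) {
            double wi = a[6] + fr * (b[6] - a[6]);
            double twi = a[7] + fr * (b[7] - a[7]);
            D.dw = (wi - W2) * twi;
            IK += gMi * W2 * (vK_[0] - V);
          } else D.dw = 0.0;
          open = a[8] + fr * (b[8] - a[8]);
        } else {
          const double* a = &wb_tab[iv * WSTR];
          const double* b = a + WSTR;
          double minf = a[0] + fr * (b[0] - a[0]);
          double ah = a[1] + fr * (b[1] - a[1]);
          double ch = a[2] + fr * (b[2] - a[2]);
          double an = a[3] + fr * (b[3] - a[3]);
          double cn = a[4] + fr * (b[4] - a[4]);
          D.dm = 0.0; D.dh = ah - ch * H; D.dn = an - cn * N;
          INa = gNa_[1] * minf * minf * minf * H * (vNa_[1] - V);
          double N2 = N * N;
          IK = gK_[1] * N2 * N2 * (vK_[1] - V);
          D.dw = 0.0;
          open = a[5] + fr * (b[5] - a[5]);
          M = minf;  // report-only
        }
        double IL = gL_[ty] * (vL_[ty] - V);
        double Isyn = gEi * (0.0 - V) + gIi * (-75.0 - V);
        D.dv = (INa + IK + IL + Iei + Isyn) / C_[ty];
        D.dq = open * (1.0 - Q) * 10.0 - Q * tdq_inv;
        D.ds = Q * (1.0 - S) * tr_inv - S * td_inv;
      };

      Deriv k1, k2, k3, k4;
      deriv(vv, mm, hh, nnn, ww, qq, ss, k1);
      deriv(vv + 0.5 * dt * k1.dv, mm + 0.5 * dt * k1.dm,
            hh + 0.5 * dt * k1.dh, nnn + 0.5 * dt * k1.dn,
            ww + 0.5 * dt * k1.dw, qq + 0.5 * dt * k1.dq,
            ss + 0.5 * dt * k1.ds, k2);
      deriv(vv + 0.5 * dt * k2.dv, mm + 0.5 * dt * k2.dm,
            hh + 0.5 * dt * k2.dh, nnn + 0.5 * dt * k2.dn,
            ww + 0.5 * dt * k2.dw, qq + 0.5 * dt * k2.dq,
            ss + 0.5 * dt * k2.ds, k3);
      deriv(vv + dt * k3.dv, mm + dt * k3.dm, hh + dt * k3.dh,
            nnn + dt * k3.dn, ww + dt * k3.dw, qq + dt * k3.dq,
            ss + dt * k3.ds, k4);

      double v_new = vv + dt / 6.0 * (k1.dv + 2 * k2.dv + 2 * k3.dv + k4.dv);
      m[i] = mm + dt / 6.0 * (k1.dm + 2 * k2.dm + 2 * k3.dm + k4.dm);
      h[i] = hh + dt / 6.0 * (k1.dh + 2 * k2.dh + 2 * k3.dh + k4.dh);
      nn[i] = nnn + dt / 6.0 * (k1.dn + 2 * k2.dn + 2 * k3.dn + k4.dn);
      w[i] = ww + dt / 6.0 * (k1.dw + 2 * k2.dw + 2 * k3.dw + k4.dw);
      q[i] = qq + dt / 6.0 * (k1.dq + 2 * k2.dq + 2 * k3.dq + k4.dq);
      s[i] = ss + dt / 6.0 * (k1.ds + 2 * k2.ds + 2 * k3.ds + k4.ds);

      if (!std::isfinite(v_new) || std::fabs(v_new) > 500.0)
        stop("unstable integration: voltage diverged at t = %f ms with step dt = %f ms",
             step * dt, dt);

      if (v_new >= -20.0 && !above[i]) {
        spike_cell.push_back(i + 1);
        spike_time.push_back((step + 1) * dt / 1000.0);
        above[i] = true;
      } else if (v_new < -20.0 && above[i]) {
        above[i] = false;
      }
      v[i] = v_new;

      if (field_pool[i])
        field_acc += gEi * (0.0 - v_new) + gIi * (-75.0 - v_new);
    }
    int ob = step / dec;
    if (ob < n_out) field[ob] += -field_acc / dec;
  }

  return List::create(_["spike_cell"] = wrap(spike_cell),
                      _["spike_time"] = wrap(spike_time),
                      _["field"] = wrap(field));
}
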
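#include <Rcpp.h>
using namespace Rcpp;

// Fixed-order parameter vector; must match .cpp_param_vector() on the R side.
enum Par {
  HR, EES_LV, V0_LV, S_LV, K_LV,
  EES_RV, V0_RV, S_RV, K_RV,
  E_LA, V0_LA, E_RA, V0_RA,
  SYS_FRAC, ACT_N1, ACT_N2, ACT_NORM,
  R_MV, R_AV, R_TV, R_PV,
  C_SA, V0_SA, R_SYS,
  C_SV, V0_SV, R_VS,
  C_PA, V0_PA, R_PUL,
  C_PV, V0_PV, R_VP,
  SPEED_RPM, HQ_A0, HQ_A1, HQ_A2,
  L_PUMP, R_OUT,
  J_IMP, KT, B_F, TC0, TC1,
  KP, KI, I_MAX,
  STEEP, P_THR, HYST, R_OPEN, R_COLL, R_EXP, TAU_ENG, TAU_REL, SUCTION_ON,
  P_FLOOR, DT_SOLVER,
  N_PAR
};

// State layout
enum St {
  iVLV, iVLA, iVRV, iVRA, iVSA, iVSV, iVPA, iVPV,
  iQP, iW, iXI, iCF, N_ST
};

static const double RPM2RAD = 2.0 * M_PI / 60.0;

struct Outputs {
  double p_lv, p_sa, p_la, p_pa, p_apex, q_sys, q_av, i_mot, power, q_est,
    p_ra, p_sv;
};

// normalized double-Hill activation, 0 at cycle start, max 1
static inline double activation_cpp(double tau, double T, const double *p) {
  double x = tau / T;
  double a1 = 0.6 * p[SYS_FRAC], a2 = p[SYS_FRAC];
  double h1 = std::pow(x / a1, p[ACT_N1]);
  h1 = h1 / (1.0 + h1);
  double h2 = 1.0 / (1.0 + std::pow(x / a2, p[ACT_N2]));
  return h1 * h2 / p[ACT_NORM];
}

static inline double ventricle_p(double v, double act, double ees, double v0,
                                 double s, double k, double floor_p,
                                 int *nfloor) {
  double pes = ees * (v - v0);
  double ped = s * expm1(k * (v - v0));
  double pr = act * pes + (1.0 - act) * ped;
  if (pr < floor_p) { pr = floor_p; (*nfloor)++; }
  return pr;
}

static void deriv(double t, const double *y, const double *p, double *dy,
                  Outputs *out, int *nfloor) {
  double T = 60.0 / p[HR];
  double tau = std::fmod(t, T);
  double act = activation_cpp(tau, T, p);

  double p_lv = ventricle_p(y[iVLV], act, p[EES_LV], p[V0_LV], p[S_LV],
                            p[K_LV], p[P_FLOOR], nfloor);
  double p_rv = ventricle_p(y[iVRV], act, p[EES_RV], p[V0_RV], p[S_RV],
                            p[K_RV], p[P_FLOOR], nfloor);
  double p_la = p[E_LA] * (y[iVLA] - p[V0_LA]);
  double p_ra = p[E_RA] * (y[iVRA] - p[V0_RA]);

  double p_sa = (y[iVSA] - p[V0_SA]) / p[C_SA];
  double p_sv = (y[iVSV] - p[V0_SV]) / p[C_SV];
  double p_pa = (y[iVPA] - p[V0_PA]) / p[C_PA];
  double p_pv = (y[iVPV] - p[V0_PV]) / p[C_PV];

  // valves (diode-resistance) and vascular beds
  double q_mv = std::max(0.0, p_la - p_lv) / p[R_MV];
  double q_av = std::max(0.0, p_lv - p_sa) / p[R_AV];
  double q_tv = std::max(0.0, p_ra - p_rv) / p[R_TV];
  double q_pvv = std::max(0.0, p_rv - p_pa) / p[R_PV];
  double q_sys = (p_sa - p_sv) / p[R_SYS];
  double q_vs = (p_sv - p_ra) / p[R_VS];
  double q_pul = (p_pa - p_pv) / p[R_PUL];
  double q_vp = (p_pv - p_la) / p[R_VP];

  // pump hydraulics
  double w = y[iW];                 // rad/s
  double wr = w / RPM2RAD;          // rpm
  double qp = y[iQP];               // mL/s
  double q_lpm = qp * 0.06;
  // quadratic loss term written as q|q| so it opposes reverse flow too
  double head = p[HQ_A0] * wr * wr + p[HQ_A1] * wr * q_lpm +
    p[HQ_A2] * q_lpm * std::fabs(q_lpm);
  double cf = y[iCF];
  // collapsing-tube resistance from open to collapsed; the exponent
  // sets how late in the collapse the throttling engages (1 = linear,
  // >1 = lumen mostly preserved until deep collapse)
  double r_in = p[R_OPEN] +
    std::pow(cf, p[R_EXP]) * (p[R_COLL] - p[R_OPEN]);
  double p_apex = p_lv - r_in * qp;
  double dqp = (head + p_apex - p_sa - p[R_OUT] * qp) / p[L_PUMP];

  // PI speed controller with anti-windup
  double err = p[SPEED_RPM] * RPM2RAD - w;
  double i_cmd = p[KP] * err + y[iXI];
  double i_mot = std::min(std::max(i_cmd, 0.0), p[I_MAX]);
  double dxi = p[KI] * err;
  if ((i_cmd >= p[I_MAX] && err > 0.0) || (i_cmd <= 0.0 && err < 0.0))
    dxi = 0.0;

  // impeller: motor torque vs hydraulic + friction torque
  double t_hyd = (p[TC0] + p[TC1] * q_lpm) * w;
  if (t_hyd < 0.0) t_hyd = 0.0;
  double dw = (p[KT] * i_mot - t_hyd - p[B_F] * w) / p[J_IMP];

  // collapsible apex: sigmoid target in LV pressure centred at the
  // collapse threshold, with buckling hysteresis -- once the tube is
  // engaging, the effective threshold rises so it reopens only at a
  // higher pressure (bistable snap-through, as in a buckled latex
  // tube); first-order relaxation toward the target
  double target = 0.0;
  if (p[SUCTION_ON] > 0.5) {
    double engage = (cf - 0.3) / 0.2;
    if (engage < 0.0) engage = 0.0;
    if (engage > 1.0) engage = 1.0;
    double thr_eff = p[P_THR] + p[HYST] * engage;
    target = 1.0 / (1.0 + std::exp(p[STEEP] * (p_lv - thr_eff)));
  }
  double tau_cf = (target > cf) ? p[TAU_ENG] : p[TAU_REL];
  double dcf = (target - cf) / tau_cf;

  dy[iVLV] = q_mv - q_av - qp;
  dy[iVLA] = q_vp - q_mv;
  dy[iVRV] = q_tv - q_pvv;
  dy[iVRA] = q_vs - q_tv;
  dy[iVSA] = q_av + qp - q_sys;
  dy[iVSV] = q_sys - q_vs;
  dy[iVPA] = q_pvv - q_pul;
  dy[iVPV] = q_pul - q_vp;
  dy[iQP] = dqp;
  dy[iW] = dw;
  dy[iXI] = dxi;
  dy[iCF] = dcf;

  if (out) {
    out->p_lv = p_lv; out->p_sa = p_sa; out->p_la = p_la; out->p_pa = p_pa;
    out->p_apex = p_apex; out->q_sys = q_sys; out->q_av = q_av;
    out->i_mot = i_mot;
    out->power = p[KT] * i_mot * w;
    out->q_est = (w > 50.0)
      ? (p[KT] * i_mot - (p[B_F] + p[TC0]) * w) / (p[TC1] * w) : 0.0;
    out->p_ra = p_ra; out->p_sv = p_sv;
  }
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector y0, NumericVector pars, double duration,
                   double t0) {
  if (pars.size() != N_PAR) stop("parameter vector has wrong length");
  if (y0.size() != N_ST) stop("state vector has wrong length");
  double p[N_PAR];
  for (int i = 0; i < N_PAR; i++) p[i] = pars[i];
  double dt = p[DT_SOLVER];
  if (dt <= 0 || dt > 1e-3) stop("dt_solver must be in (0, 1e-3] s");
  int nsub = (int)std::lround(1e-3 / dt);
  dt = 1e-3 / nsub; // exact 1-ms record grid

  int nrec = (int)std::lround(duration * 1000.0);
  const int NCOL = 19;
  NumericMatrix rec(nrec, NCOL);

  double y[N_ST], k1[N_ST], k2[N_ST], k3[N_ST], k4[N_ST], yt[N_ST];
  for (int i = 0; i < N_ST; i++) y[i] = y0[i];
  int nfloor = 0;
  Outputs out;
  double t = t0;

  for (int ir = 0; ir < nrec; ir++) {
    deriv(t, y, p, k1, &out, &nfloor);
    double vtot = y[iVLV] + y[iVLA] + y[iVRV] + y[iVRA] + y[iVSA] +
      y[iVSV] + y[iVPA] + y[iVPV];
    double T = 60.0 / p[HR];
    rec(ir, 0) = t;
    rec(ir, 1) = out.p_lv;
    rec(ir, 2) = out.p_sa;
    rec(ir, 3) = out.p_la;
    rec(ir, 4) = out.p_pa;
    rec(ir, 5) = out.p_apex;
    rec(ir, 6) = y[iVLV];
    rec(ir, 7) = vtot;
    rec(ir, 8) = out.q_sys;
    rec(ir, 9) = y[iQP];
    rec(ir, 10) = out.q_av;
    rec(ir, 11) = y[iW] / RPM2RAD;
    rec(ir, 12) = out.i_mot;
    rec(ir, 13) = out.power;
    rec(ir, 14) = out.q_est;
    rec(ir, 15) = y[iCF];
    rec(ir, 16) = activation_cpp(std::fmod(t, T), T, p);
    rec(ir, 17) = out.p_ra;
    rec(ir, 18) = out.p_sv;

    for (int is = 0; is < nsub; is++) {
      deriv(t, y, p, k1, NULL, &nfloor);
      for (int i = 0; i < N_ST; i++) yt[i] = y[i] + 0.5 * dt * k1[i];
      deriv(t + 0.5 * dt, yt, p, k2, NULL, &nfloor);
      for (int i = 0; i < N_ST; i++) yt[i] = y[i] + 0.5 * dt * k2[i];
      deriv(t + 0.5 * dt, yt, p, k3, NULL, &nfloor);
      for (int i = 0; i < N_ST; i++) yt[i] = y[i] + dt * k3[i];
      deriv(t + dt, yt, p, k4, NULL, &nfloor);
      for (int i = 0; i < N_ST; i++)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (y[iCF] < 0.0) y[iCF] = 0.0;
      if (y[iCF] > 1.0) y[iCF] = 1.0;
      t += dt;
      if (!std::isfinite(y[iVLV]) || !std::isfinite(y[iQP]) ||
          !std::isfinite(y[iW]))
        stop("numerical error: non-finite state at t = %f s", t);
      if (y[iW] <= 0.0)
        stop("pump stall: impeller speed reached zero at t = %f s", t);
    }
    t = t0 + (ir + 1) * 1e-3; // avoid drift accumulation
  }

  NumericVector yout(N_ST);
  for (int i = 0; i < N_ST; i++) yout[i] = y[i];
  colnames(rec) = CharacterVector::create(
    "t", "p_lv", "p_sa", "p_la", "p_pa", "p_apex", "v_lv", "v_total",
    "q_sys", "q_pump", "q_av", "omega_rpm", "current", "power",
    "q_est_raw", "collapse_fraction", "activation", "p_ra", "p_sv");
  return List::create(_["signals"] = rec, _["state"] = yout,
                      _["t_end"] = t, _["n_floor"] = nfloor);
}
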
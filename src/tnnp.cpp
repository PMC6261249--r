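#include "tnnp.h"

using namespace Rcpp;

TnnpParams tnnp_params_from(const NumericVector& p) {
  TnnpParams q;
  q.g_na = p["g_na"]; q.g_k1 = p["g_k1"]; q.g_to = p["g_to"];
  q.g_kr = p["g_kr"]; q.g_ks = p["g_ks"]; q.g_cal = p["g_cal"];
  q.k_naca = p["k_naca"]; q.p_nak = p["p_nak"];
  q.g_pca = p["g_pca"]; q.g_pk = p["g_pk"];
  q.g_bca = p["g_bca"]; q.g_bna = p["g_bna"];
  q.cm = p["cm"]; q.cm_ca = p["cm_ca"];
  q.v_leak = p["v_leak"]; q.vmax_up = p["vmax_up"]; q.k_up = p["k_up"];
  q.a_rel = p["a_rel"]; q.b_rel = p["b_rel"]; q.c_rel = p["c_rel"];
  q.buf_c = p["buf_c"]; q.k_bufc = p["k_bufc"];
  q.buf_sr = p["buf_sr"]; q.k_bufsr = p["k_bufsr"];
  q.v_c = p["v_c"]; q.v_sr = p["v_sr"];
  q.rgas = p["rgas"]; q.temp = p["temp"]; q.faraday = p["faraday"];
  q.na_o = p["na_o"]; q.k_o = p["k_o"]; q.ca_o = p["ca_o"];
  q.p_kna = p["p_kna"];
  q.km_k = p["km_k"]; q.km_na = p["km_na"]; q.km_nai = p["km_nai"];
  q.km_ca = p["km_ca"]; q.k_sat = p["k_sat"];
  q.alpha_naca = p["alpha_naca"]; q.gamma_naca = p["gamma_naca"];
  q.kp_ca = p["kp_ca"];
  q.s_epi_kinetics = (int) p["s_epi_kinetics"];
  return q;
}

TnnpCurrents tnnp_currents(const double* y, const TnnpParams& p) {
  const double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4], f = y[5],
               fca = y[6], r = y[7], s = y[8], xr1 = y[9], xr2 = y[10],
               xs = y[11], cai = y[13], nai = y[15], ki = y[16];
  const double rtf = p.rgas * p.temp / p.faraday;
  const double ena = rtf * std::log(p.na_o / nai);
  const double ek  = rtf * std::log(p.k_o / ki);
  const double eks = rtf * std::log((p.k_o + p.p_kna * p.na_o) /
                                    (ki + p.p_kna * nai));
  const double eca = 0.5 * rtf * std::log(p.ca_o / cai);

  TnnpCurrents c;
  c.i_na = p.g_na * m * m * m * h * j * (V - ena);

  // inward rectifier
  const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - ek - 200.0)));
  const double bk1 = (3.0 * std::exp(0.0002 * (V - ek + 100.0)) +
                      std::exp(0.1 * (V - ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - ek)));
  c.i_k1 = p.g_k1 * std::sqrt(p.k_o / 5.4) * (ak1 / (ak1 + bk1)) * (V - ek);

  c.i_to = p.g_to * r * s * (V - ek);
  c.i_kr = p.g_kr * std::sqrt(p.k_o / 5.4) * xr1 * xr2 * (V - ek);
  c.i_ks = p.g_ks * xs * xs * (V - eks);

  // L-type Ca current (GHK-like driving term, guarded at V = 0)
  const double z = 2.0 * V / rtf;
  double drive;
  if (std::fabs(z) < 1e-6) {
    drive = 2.0 * p.faraday * (cai - 0.341 * p.ca_o);
  } else {
    drive = 2.0 * p.faraday * z * (cai * std::exp(z) - 0.341 * p.ca_o) /
            (std::exp(z) - 1.0);
  }
  c.i_cal = p.g_cal * d * f * fca * drive;

  const double vfrt = V / rtf;
  const double na_o3 = p.na_o * p.na_o * p.na_o;
  const double nai3 = nai * nai * nai;
  c.i_naca = p.k_naca *
             (std::exp(p.gamma_naca * vfrt) * nai3 * p.ca_o -
              std::exp((p.gamma_naca - 1.0) * vfrt) * na_o3 * cai *
                  p.alpha_naca) /
             ((p.km_nai * p.km_nai * p.km_nai + na_o3) * (p.km_ca + p.ca_o) *
              (1.0 + p.k_sat * std::exp((p.gamma_naca - 1.0) * vfrt)));

  c.i_nak = p.p_nak * p.k_o * nai /
            ((p.k_o + p.km_k) * (nai + p.km_na) *
             (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
              0.0353 * std::exp(-vfrt)));

  c.i_pca = p.g_pca * cai / (cai + p.kp_ca);
  c.i_pk = p.g_pk * (V - ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.i_bca = p.g_bca * (V - eca);
  c.i_bna = p.g_bna * (V - ena);

  c.i_ion = c.i_na + c.i_k1 + c.i_to + c.i_kr + c.i_ks + c.i_cal + c.i_naca +
            c.i_nak + c.i_pca + c.i_pk + c.i_bca + c.i_bna;
  return c;
}

TnnpFluxes tnnp_fluxes(const double* y, const TnnpParams& p,
                       const TnnpCurrents& cur) {
  const double d = y[4], g = y[12], cai = y[13], casr = y[14];
  TnnpFluxes fl;
  fl.i_leak = p.v_leak * (casr - cai);
  fl.i_up = p.vmax_up / (1.0 + (p.k_up * p.k_up) / (cai * cai));
  fl.i_rel = d * g *
             (p.a_rel * casr * casr / (p.b_rel * p.b_rel + casr * casr) +
              p.c_rel);
  fl.ca_i_bufc = cai * p.buf_c / (cai + p.k_bufc);
  fl.ca_sr_bufsr = casr * p.buf_sr / (casr + p.k_bufsr);
  fl.dca_i_total =
      -(cur.i_cal + cur.i_bca + cur.i_pca - 2.0 * cur.i_naca) * p.cm_ca /
          (2.0 * p.v_c * p.faraday) +
      fl.i_leak - fl.i_up + fl.i_rel;
  fl.dca_sr_total = (p.v_c / p.v_sr) * (fl.i_up - fl.i_leak - fl.i_rel);
  return fl;
}

// gate steady states and time constants
static inline void gate_m(double V, double& xinf, double& tau) {
  double t = 1.0 + std::exp((-56.86 - V) / 9.03);
  xinf = 1.0 / (t * t);
  double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
             0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  tau = a * b;
}

static inline void gate_h(double V, double& xinf, double& tau) {
  double t = 1.0 + std::exp((V + 71.55) / 7.43);
  xinf = 1.0 / (t * t);
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.057 * std::exp(-(V + 80.0) / 6.8);
    b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  tau = 1.0 / (a + b);
}

static inline void gate_j(double V, double& xinf, double& tau) {
  double t = 1.0 + std::exp((V + 71.55) / 7.43);
  xinf = 1.0 / (t * t);
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.02424 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  tau = 1.0 / (a + b);
}

static inline void gate_d(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
  double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  tau = a * b + c;
}

static inline void gate_f(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  tau = 1125.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
        165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
}

static inline double fca_inf(double cai) {
  double a = 1.0 / (1.0 + std::pow(cai / 0.000325, 8.0));
  double b = 0.1 / (1.0 + std::exp((cai - 0.0005) / 0.0001));
  double c = 0.2 / (1.0 + std::exp((cai - 0.00075) / 0.0008));
  double f = (a + b + c + 0.23) / 1.46;
  // the printed steady state slightly exceeds 1 at diastolic calcium;
  // clamp so the gate stays a fraction in [0, 1]
  return f > 1.0 ? 1.0 : f;
}

static inline double g_inf(double cai) {
  if (cai < 0.00035) {
    double q = cai / 0.00035;
    double q2 = q * q;
    return 1.0 / (1.0 + q2 * q2 * q2);
  }
  double q = cai / 0.00035;
  double q4 = q * q * q * q;
  return 1.0 / (1.0 + q4 * q4 * q4 * q4);
}

static inline void gate_r(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
}

static inline void gate_s(double V, int epi, double& xinf, double& tau) {
  if (epi) {
    xinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
          5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  } else {
    xinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    tau = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  }
}

static inline void gate_xr1(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  tau = a * b;
}

static inline void gate_xr2(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  tau = a * b;
}

static inline void gate_xs(double V, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double a = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
  double b = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
  tau = a * b;
}

void tnnp_rhs(const double* y, const TnnpParams& p, double istim, double* dy) {
  const double V = y[0];
  TnnpCurrents cur = tnnp_currents(y, p);
  TnnpFluxes fl = tnnp_fluxes(y, p, cur);

  dy[0] = -(cur.i_ion + istim) / p.cm;

  double xinf, tau;
  gate_m(V, xinf, tau);   dy[1] = (xinf - y[1]) / tau;
  gate_h(V, xinf, tau);   dy[2] = (xinf - y[2]) / tau;
  gate_j(V, xinf, tau);   dy[3] = (xinf - y[3]) / tau;
  gate_d(V, xinf, tau);   dy[4] = (xinf - y[4]) / tau;
  gate_f(V, xinf, tau);   dy[5] = (xinf - y[5]) / tau;

  // Ca-dependent inactivation gates only relax downward at depolarized V
  double fcai = fca_inf(y[13]);
  dy[6] = (fcai > y[6] && V > -60.0) ? 0.0 : (fcai - y[6]) / 2.0;
  double gi = g_inf(y[13]);
  dy[12] = (gi > y[12] && V > -60.0) ? 0.0 : (gi - y[12]) / 2.0;

  gate_r(V, xinf, tau);   dy[7] = (xinf - y[7]) / tau;
  gate_s(V, p.s_epi_kinetics, xinf, tau); dy[8] = (xinf - y[8]) / tau;
  gate_xr1(V, xinf, tau); dy[9] = (xinf - y[9]) / tau;
  gate_xr2(V, xinf, tau); dy[10] = (xinf - y[10]) / tau;
  gate_xs(V, xinf, tau);  dy[11] = (xinf - y[11]) / tau;

  const double cai = y[13], casr = y[14];
  const double bufc_fac =
      1.0 / (1.0 + p.buf_c * p.k_bufc / ((cai + p.k_bufc) * (cai + p.k_bufc)));
  const double bufsr_fac =
      1.0 / (1.0 + p.buf_sr * p.k_bufsr /
                       ((casr + p.k_bufsr) * (casr + p.k_bufsr)));
  dy[13] = bufc_fac * fl.dca_i_total;
  dy[14] = bufsr_fac * fl.dca_sr_total;

  const double vcf = p.v_c * p.faraday;
  dy[15] = -(cur.i_na + cur.i_bna + 3.0 * cur.i_nak + 3.0 * cur.i_naca) *
           p.cm_ca / vcf;
  dy[16] = -(cur.i_k1 + cur.i_to + cur.i_kr + cur.i_ks - 2.0 * cur.i_nak +
             cur.i_pk + istim) *
           p.cm_ca / vcf;
}

// Rush-Larsen exponential update for one gate
static inline double rl(double x, double xinf, double tau, double dt) {
  return xinf - (xinf - x) * std::exp(-dt / tau);
}

static void tnnp_advance(double* y, const TnnpParams& p, double istim,
                         double dt, const TnnpCurrents& cur,
                         const TnnpFluxes& fl) {
  const double V = y[0];
  double xinf, tau;
  gate_m(V, xinf, tau);   y[1] = rl(y[1], xinf, tau, dt);
  gate_h(V, xinf, tau);   y[2] = rl(y[2], xinf, tau, dt);
  gate_j(V, xinf, tau);   y[3] = rl(y[3], xinf, tau, dt);
  gate_d(V, xinf, tau);   y[4] = rl(y[4], xinf, tau, dt);
  gate_f(V, xinf, tau);   y[5] = rl(y[5], xinf, tau, dt);
  gate_r(V, xinf, tau);   y[7] = rl(y[7], xinf, tau, dt);
  gate_s(V, p.s_epi_kinetics, xinf, tau); y[8] = rl(y[8], xinf, tau, dt);
  gate_xr1(V, xinf, tau); y[9] = rl(y[9], xinf, tau, dt);
  gate_xr2(V, xinf, tau); y[10] = rl(y[10], xinf, tau, dt);
  gate_xs(V, xinf, tau);  y[11] = rl(y[11], xinf, tau, dt);

  double fcai = fca_inf(y[13]);
  double fca_new = rl(y[6], fcai, 2.0, dt);
  if (!(fca_new > y[6] && V > -60.0)) y[6] = fca_new;
  double gi = g_inf(y[13]);
  double g_new = rl(y[12], gi, 2.0, dt);
  if (!(g_new > y[12] && V > -60.0)) y[12] = g_new;

  const double cai = y[13], casr = y[14];
  const double bufc_fac =
      1.0 / (1.0 + p.buf_c * p.k_bufc / ((cai + p.k_bufc) * (cai + p.k_bufc)));
  const double bufsr_fac =
      1.0 / (1.0 + p.buf_sr * p.k_bufsr /
                       ((casr + p.k_bufsr) * (casr + p.k_bufsr)));
  y[13] += dt * bufc_fac * fl.dca_i_total;
  y[14] += dt * bufsr_fac * fl.dca_sr_total;

  const double vcf = p.v_c * p.faraday;
  y[15] += dt * (-(cur.i_na + cur.i_bna + 3.0 * cur.i_nak +
                   3.0 * cur.i_naca) * p.cm_ca / vcf);
  y[16] += dt * (-(cur.i_k1 + cur.i_to + cur.i_kr + cur.i_ks -
                   2.0 * cur.i_nak + cur.i_pk + istim) * p.cm_ca / vcf);

  y[0] += dt * (-(cur.i_ion + istim) / p.cm);
}

void tnnp_step(double* y, const TnnpParams& p, double istim, double dt,
               double dv_max) {
  double remaining = dt;
  const double h_min = dt / 64.0;
  while (remaining > 1e-12) {
    // cap the voltage change per substep (tight steps during the upstroke)
    TnnpCurrents cur = tnnp_currents(y, p);
    TnnpFluxes fl = tnnp_fluxes(y, p, cur);
    double dvdt = std::fabs(-(cur.i_ion + istim) / p.cm);
    double h = remaining;
    if (dvdt * h > dv_max) {
      h = dv_max / dvdt;
      if (h < h_min) h = h_min;
      if (h > remaining) h = remaining;
    }
    tnnp_advance(y, p, istim, h, cur, fl);
    remaining -= h;
  }
}

// [[Rcpp::export]]
NumericVector tnnp_currents_cpp(NumericVector state, NumericVector params) {
  TnnpParams p = tnnp_params_from(params);
  TnnpCurrents c = tnnp_currents(REAL(state), p);
  return NumericVector::create(
      _["i_na"] = c.i_na, _["i_k1"] = c.i_k1, _["i_to"] = c.i_to,
      _["i_kr"] = c.i_kr, _["i_ks"] = c.i_ks, _["i_cal"] = c.i_cal,
      _["i_naca"] = c.i_naca, _["i_nak"] = c.i_nak, _["i_pca"] = c.i_pca,
      _["i_pk"] = c.i_pk, _["i_bca"] = c.i_bca, _["i_bna"] = c.i_bna,
      _["i_ion"] = c.i_ion);
}

// [[Rcpp::export]]
List tnnp_fluxes_cpp(NumericVector state, NumericVector params) {
  TnnpParams p = tnnp_params_from(params);
  TnnpCurrents c = tnnp_currents(REAL(state), p);
  TnnpFluxes fl = tnnp_fluxes(REAL(state), p, c);
  return List::create(
      _["i_leak"] = fl.i_leak, _["i_up"] = fl.i_up, _["i_rel"] = fl.i_rel,
      _["dca_i_total"] = fl.dca_i_total, _["dca_sr_total"] = fl.dca_sr_total,
      _["ca_i_bufc"] = fl.ca_i_bufc, _["ca_sr_bufsr"] = fl.ca_sr_bufsr);
}

// [[Rcpp::export]]
NumericVector tnnp_rhs_cpp(NumericVector state, NumericVector params,
                           double istim) {
  TnnpParams p = tnnp_params_from(params);
  NumericVector dy(TNNP_NSTATE);
  tnnp_rhs(REAL(state), p, istim, REAL(dy));
  return dy;
}

// [[Rcpp::export]]
NumericVector tnnp_step_cpp(NumericVector state, NumericVector params,
                            double istim, double dt, double dv_max) {
  TnnpParams p = tnnp_params_from(params);
  NumericVector y = clone(state);
  tnnp_step(REAL(y), p, istim, dt, dv_max);
  return y;
}

// [[Rcpp::export]]
List run_paced_cell_cpp(NumericVector state0, NumericVector params,
                        double bcl, int n_beats, double dt, double stim_amp,
                        double stim_dur, double sample_dt, double dv_max) {
  TnnpParams p = tnnp_params_from(params);
  std::vector<double> y(state0.begin(), state0.end());

  const long steps_per_beat = (long) std::llround(bcl / dt);
  const long sample_every = std::max(1L, (long) std::llround(sample_dt / dt));
  const long n_total = steps_per_beat * (long) n_beats;
  const long n_samp = (n_beats == 0) ? 0 : (n_total / sample_every + 1);

  NumericVector t_out(n_samp), v_out(n_samp), cai_out(n_samp),
      casr_out(n_samp), nai_out(n_samp), ki_out(n_samp), leak_out(n_samp),
      up_out(n_samp), rel_out(n_samp);
  IntegerVector beat_out(n_samp);
  NumericVector peak_v(n_beats), peak_cai(n_beats);

  long isamp = 0;
  for (int b = 0; b < n_beats; ++b) {
    double pv = -1e9, pcai = -1e9;
    for (long k = 0; k < steps_per_beat; ++k) {
      double t_in_beat = k * dt;
      double t_abs = b * bcl + t_in_beat;
      if ((b * steps_per_beat + k) % sample_every == 0) {
        TnnpCurrents cur = tnnp_currents(y.data(), p);
        TnnpFluxes fl = tnnp_fluxes(y.data(), p, cur);
        t_out[isamp] = t_abs; v_out[isamp] = y[0]; cai_out[isamp] = y[13];
        casr_out[isamp] = y[14]; nai_out[isamp] = y[15]; ki_out[isamp] = y[16];
        leak_out[isamp] = fl.i_leak; up_out[isamp] = fl.i_up;
        rel_out[isamp] = fl.i_rel; beat_out[isamp] = b + 1;
        ++isamp;
      }
      double istim =
          (t_in_beat < stim_dur) ? stim_amp : 0.0;
      tnnp_step(y.data(), p, istim, dt, dv_max);
      if (y[0] > pv) pv = y[0];
      if (y[13] > pcai) pcai = y[13];
    }
    peak_v[b] = pv; peak_cai[b] = pcai;
  }
  if (n_samp > 0 && isamp < n_samp) {
    // final sample at end of run
    TnnpCurrents cur = tnnp_currents(y.data(), p);
    TnnpFluxes fl = tnnp_fluxes(y.data(), p, cur);
    t_out[isamp] = n_beats * bcl; v_out[isamp] = y[0]; cai_out[isamp] = y[13];
    casr_out[isamp] = y[14]; nai_out[isamp] = y[15]; ki_out[isamp] = y[16];
    leak_out[isamp] = fl.i_leak; up_out[isamp] = fl.i_up;
    rel_out[isamp] = fl.i_rel; beat_out[isamp] = n_beats;
  }

  return List::create(
      _["time"] = t_out, _["v"] = v_out, _["ca_i"] = cai_out,
      _["ca_sr"] = casr_out, _["na_i"] = nai_out, _["k_i"] = ki_out,
      _["i_leak"] = leak_out, _["i_up"] = up_out, _["i_rel"] = rel_out,
      _["beat"] = beat_out, _["peak_v"] = peak_v, _["peak_ca_i"] = peak_cai,
      _["final_state"] = NumericVector(y.begin(), y.end()));
}
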
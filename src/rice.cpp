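#include "rice.h"

using namespace Rcpp;

static inline double qfac(double q, double tmpc) {
  return std::pow(q, (tmpc - 37.0) / 10.0);
}

RiceParams rice_params_from(const NumericVector& p) {
  RiceParams q;
  q.kon = p["kon"]; q.koffl = p["koffl"]; q.koffh = p["koffh"];
  q.perm50 = p["perm50"]; q.nperm = p["nperm"];
  q.kn_p = p["kn_p"]; q.kp_n = p["kp_n"];
  q.fapp = p["fapp"]; q.gapp = p["gapp"]; q.gslmod = p["gslmod"];
  q.hf = p["hf"]; q.hfmdc = p["hfmdc"]; q.hb = p["hb"]; q.hbmdc = p["hbmdc"];
  q.gxb = p["gxb"]; q.sigmap = p["sigmap"]; q.sigman = p["sigman"];
  q.xbmodsp = p["xbmodsp"];
  q.qkon = p["qkon"]; q.qkoff = p["qkoff"]; q.qkn_p = p["qkn_p"];
  q.qkp_n = p["qkp_n"]; q.qfapp = p["qfapp"]; q.qgapp = p["qgapp"];
  q.qhf = p["qhf"]; q.qhb = p["qhb"]; q.qgxb = p["qgxb"];
  q.tmpc = p["tmpc"];
  q.sl_max = p["sl_max"]; q.sl_min = p["sl_min"];
  q.len_thin = p["len_thin"]; q.len_thick = p["len_thick"];
  q.len_hbare = p["len_hbare"];
  q.x_0 = p["x_0"]; q.x_psi = p["x_psi"];
  q.pcon_t = p["pcon_t"]; q.pexp_t = p["pexp_t"]; q.sl_rest = p["sl_rest"];
  q.pcon_c = p["pcon_c"]; q.pexp_c = p["pexp_c"]; q.sl_c = p["sl_c"];
  q.passive_scale = p["passive_scale"];
  q.sl0 = p["sl0"]; q.kse = p["kse"]; q.visc = p["visc"]; q.mass = p["mass"];

  q.kon_t = q.kon * qfac(q.qkon, q.tmpc);
  q.koffl_t = q.koffl * qfac(q.qkoff, q.tmpc);
  q.koffh_t = q.koffh * qfac(q.qkoff, q.tmpc);
  q.kn_p_t = q.kn_p * qfac(q.qkn_p, q.tmpc);
  q.kp_n_t = q.kp_n * qfac(q.qkp_n, q.tmpc);
  q.fapp_t = q.fapp * q.xbmodsp * qfac(q.qfapp, q.tmpc);
  q.gapp_base_t = q.gapp * q.xbmodsp * qfac(q.qgapp, q.tmpc);
  q.hf_base_t = q.hf * q.xbmodsp * qfac(q.qhf, q.tmpc);
  q.hb_base_t = q.hb * q.xbmodsp * qfac(q.qhb, q.tmpc);
  q.gxb_base_t = q.gxb * q.xbmodsp * qfac(q.qgxb, q.tmpc);

  // steady-state duty fractions of the three-state cycle at base rates
  double f = q.fapp, g = q.gapp, h1 = q.hf, h2 = q.hb, gx = q.gxb;
  double den = gx * h1 + f * h1 + gx * g + h2 * f + h2 * g + gx * f;
  q.ss_xb_prer = (h2 * f + gx * f) / den;
  q.ss_xb_postr = f * h1 / den;
  q.fnorm = q.x_0 * q.ss_xb_postr;  // normalization of active force
  return q;
}

static inline double passive_force(double sl, const RiceParams& p) {
  double d = sl - p.sl_rest;
  double f = (d >= 0.0 ? 1.0 : -1.0) * p.pcon_t *
             (std::exp(p.pexp_t * std::fabs(d)) - 1.0);
  if (sl > p.sl_c)
    f += p.pcon_c * (std::exp(p.pexp_c * (sl - p.sl_c)) - 1.0);
  return p.passive_scale * f;
}

static inline void overlap(double sl, const RiceParams& p, double& thick,
                           double& thin) {
  double sovr_ze = std::min(p.len_thick / 2.0, sl / 2.0);
  double sovr_cle = std::max(sl / 2.0 - (sl - p.len_thin), p.len_hbare / 2.0);
  double len_sovr = std::max(0.0, sovr_ze - sovr_cle);
  thick = len_sovr * 2.0 / (p.len_thick - p.len_hbare);
  thin = len_sovr / p.len_thin;
}

RiceDerived rice_derived(const double* y, const RiceParams& p) {
  RiceDerived d;
  const double sl = y[7];
  overlap(sl, p, d.sovf_thick, d.sovf_thin);

  const double perm =
      (1.0 - d.sovf_thin) * y[0] + d.sovf_thin * y[1];
  double inv = std::pow(p.perm50 / std::max(perm, 1e-9), p.nperm);
  d.permtot = std::sqrt(1.0 / (1.0 + inv));

  const double x1 = y[5], x2 = y[6];
  double gxbmd = (x2 < p.x_0)
                     ? std::exp(p.sigmap * ((p.x_0 - x2) / p.x_0) *
                                ((p.x_0 - x2) / p.x_0))
                     : std::exp(p.sigman * ((x2 - p.x_0) / p.x_0) *
                                ((x2 - p.x_0) / p.x_0));
  d.gxb_t = p.gxb_base_t * gxbmd;

  d.f_active = d.sovf_thick * (x1 * y[3] + x2 * y[4]) / p.fnorm;
  d.f_passive = passive_force(sl, p);
  return d;
}

void rice_init_state(double* y, const RiceParams& p, double ca_dia) {
  double al = p.kon_t * ca_dia, ah = p.kon_t * ca_dia;
  y[0] = al / (al + p.koffl_t);
  y[1] = ah / (ah + p.koffh_t);
  y[2] = 0.99;            // nonpermissive
  y[3] = 0.0;             // pre-rotated
  y[4] = 0.0;             // post-rotated
  y[5] = 0.0;
  y[6] = p.x_0;
  y[7] = p.sl0;
  y[8] = 0.0;
}

// exponential update for dx/dt = b - a*x (a > 0), else forward Euler
static inline double exp_update(double x, double a, double b, double dt) {
  if (a * dt < 1e-8) return x + dt * (b - a * x);
  double xinf = b / a;
  return xinf + (x - xinf) * std::exp(-a * dt);
}

void rice_step(double* y, double ca, const RiceParams& p, double dt, int mode,
               double ext_load) {
  double thick, thin;
  const double sl = y[7];
  overlap(sl, p, thick, thin);

  // troponin Ca binding (low/high affinity pools)
  double bon = p.kon_t * ca;
  y[0] = exp_update(y[0], bon + p.koffl_t, bon, dt);
  y[1] = exp_update(y[1], bon + p.koffh_t, bon, dt);

  // regulatory unit permissiveness
  double perm = (1.0 - thin) * y[0] + thin * y[1];
  double inv = std::pow(p.perm50 / std::max(perm, 1e-9), p.nperm);
  double permtot = std::sqrt(1.0 / (1.0 + inv));
  double inprmt = std::min(1.0 / permtot, 100.0);

  // strain-modulated rates
  const double x1 = y[5], x2 = y[6];
  double hfmd = std::exp(-((x1 >= 0.0) ? 1.0 : -1.0) * p.hfmdc *
                         (x1 / p.x_0) * (x1 / p.x_0));
  double hbmd = std::exp(((x2 - p.x_0 >= 0.0) ? 1.0 : -1.0) * p.hbmdc *
                         ((x2 - p.x_0) / p.x_0) * ((x2 - p.x_0) / p.x_0));
  double gxbmd =
      (x2 < p.x_0)
          ? std::exp(p.sigmap * ((p.x_0 - x2) / p.x_0) * ((p.x_0 - x2) / p.x_0))
          : std::exp(p.sigman * ((x2 - p.x_0) / p.x_0) * ((x2 - p.x_0) / p.x_0));
  double gapslmd = 1.0 + (1.0 - thick) * p.gslmod;
  double fapp_t = p.fapp_t;
  double gapp_t = p.gapp_base_t * gapslmd;
  double hf_t = p.hf_base_t * hfmd;
  double hb_t = p.hb_base_t * hbmd;
  double gxb_t = p.gxb_base_t * gxbmd;

  // cross-bridge state occupancies (P treated explicitly within the step)
  double n = y[2], xbprer = y[3], xbpostr = y[4];
  double pfree = std::max(0.0, 1.0 - n - xbprer - xbpostr);
  double n_new = exp_update(
      n, p.kn_p_t * permtot + p.kp_n_t * inprmt,
      p.kp_n_t * inprmt * (1.0 - xbprer - xbpostr), dt);
  double xbprer_new = exp_update(
      xbprer, fapp_t + gapp_t + hf_t,
      fapp_t * (1.0 - n - xbpostr) + hb_t * xbpostr, dt);
  double xbpostr_new =
      exp_update(xbpostr, hb_t + gxb_t, hf_t * xbprer, dt);
  (void) pfree;
  y[2] = n_new; y[3] = xbprer_new; y[4] = xbpostr_new;

  // sarcomere length dynamics (printed-integral formulation, signed forces)
  double dsl = 0.0;
  if (mode == 1) {
    dsl = (y[8] + (p.sl0 - sl) * p.visc) / p.mass;
    double f_act_signed = -thick * (x1 * xbprer + x2 * xbpostr) / p.fnorm;
    double f_pas_signed = -passive_force(sl, p);
    double f_preload_signed = -passive_force(p.sl0, p);
    double f_after = p.kse * (sl - p.sl0) - ext_load;
    y[8] += dt * (f_act_signed + f_pas_signed - f_preload_signed - f_after);
    double sl_new = sl + dt * ((y[8] + (p.sl0 - sl) * p.visc) / p.mass);
    y[7] = std::min(p.sl_max, std::max(p.sl_min, sl_new));
  }

  // mean distortions of attached cross-bridges
  double a1 = (p.x_psi / p.ss_xb_prer) * (fapp_t + hb_t);
  double b1 = dsl / 2.0 + (p.x_psi / p.ss_xb_prer) * hb_t * (x2 - p.x_0);
  y[5] = exp_update(x1, a1, b1, dt);
  double a2 = (p.x_psi / p.ss_xb_postr) * hf_t;
  double b2 = dsl / 2.0 + a2 * (x1 + p.x_0);
  // note b2 uses the pre-update x1 for consistency of the explicit coupling
  y[6] = exp_update(x2, a2, b2, dt);
}

// linear interpolation of the Ca transient, repeating with period cycle_ms
static inline double ca_lookup(double t, double cycle_ms,
                               const std::vector<double>& ct,
                               const std::vector<double>& cv) {
  double tm = t - cycle_ms * std::floor(t / cycle_ms);
  size_t n = ct.size();
  if (tm <= ct[0]) return cv[0];
  if (tm >= ct[n - 1]) return cv[n - 1];
  size_t lo = (size_t)((tm - ct[0]) / (ct[1] - ct[0]));  // uniform grid
  if (lo >= n - 1) lo = n - 2;
  while (lo > 0 && ct[lo] > tm) --lo;
  while (lo < n - 2 && ct[lo + 1] < tm) ++lo;
  double w = (tm - ct[lo]) / (ct[lo + 1] - ct[lo]);
  return cv[lo] * (1.0 - w) + cv[lo + 1] * w;
}

// [[Rcpp::export]]
List rice_twitch_cpp(NumericVector params, NumericVector ca_time,
                     NumericVector ca_value, double cycle_ms, int n_cycles,
                     double dt, int mode, double sample_dt) {
  RiceParams p = rice_params_from(params);
  std::vector<double> ct(ca_time.begin(), ca_time.end());
  std::vector<double> cv(ca_value.begin(), ca_value.end());
  double y[RICE_NSTATE];
  rice_init_state(y, p, cv.empty() ? 0.1 : cv[0]);

  const long steps_per_cycle = (long) std::llround(cycle_ms / dt);
  const long sample_every = std::max(1L, (long) std::llround(sample_dt / dt));
  const long n_total = steps_per_cycle * (long) n_cycles;
  const long n_samp = (n_cycles == 0) ? 0 : (n_total / sample_every + 1);

  NumericVector t_out(n_samp), sl_out(n_samp), strain_out(n_samp),
      tens_out(n_samp), pas_out(n_samp), e_out(n_samp), gxb_out(n_samp),
      sovf_out(n_samp), ca_out(n_samp), intf_out(n_samp);
  IntegerVector cyc_out(n_samp);

  long isamp = 0;
  for (long k = 0; k < n_total; ++k) {
    double t = k * dt;
    if (k % sample_every == 0) {
      RiceDerived d = rice_derived(y, p);
      t_out[isamp] = t; sl_out[isamp] = y[7];
      strain_out[isamp] = (y[7] - p.sl0) / p.sl0;
      tens_out[isamp] = d.f_active; pas_out[isamp] = d.f_passive;
      gxb_out[isamp] = d.gxb_t * 1000.0;  // 1/s
      sovf_out[isamp] = d.sovf_thick;
      e_out[isamp] = d.gxb_t * 1000.0 * d.sovf_thick;
      ca_out[isamp] = ca_lookup(t, cycle_ms, ct, cv);
      intf_out[isamp] = y[8];
      cyc_out[isamp] = (int)(k / steps_per_cycle) + 1;
      ++isamp;
    }
    double ca = ca_lookup(t, cycle_ms, ct, cv);
    rice_step(y, ca, p, dt, mode, 0.0);
  }
  if (n_samp > 0 && isamp < n_samp) {
    RiceDerived d = rice_derived(y, p);
    double t = n_total * dt;
    t_out[isamp] = t; sl_out[isamp] = y[7];
    strain_out[isamp] = (y[7] - p.sl0) / p.sl0;
    tens_out[isamp] = d.f_active; pas_out[isamp] = d.f_passive;
    gxb_out[isamp] = d.gxb_t * 1000.0; sovf_out[isamp] = d.sovf_thick;
    e_out[isamp] = d.gxb_t * 1000.0 * d.sovf_thick;
    ca_out[isamp] = ca_lookup(t, cycle_ms, ct, cv);
    intf_out[isamp] = y[8]; cyc_out[isamp] = n_cycles;
  }

  return List::create(
      _["time"] = t_out, _["sl"] = sl_out, _["strain"] = strain_out,
      _["tension"] = tens_out, _["f_passive"] = pas_out, _["e_rate"] = e_out,
      _["gxb_t"] = gxb_out, _["sovf_thick"] = sovf_out, _["ca"] = ca_out,
      _["integral_force"] = intf_out, _["cycle"] = cyc_out);
}

// [[Rcpp::export]]
List rice_derived_cpp(NumericVector state, NumericVector params) {
  RiceParams p = rice_params_from(params);
  RiceDerived d = rice_derived(REAL(state), p);
  return List::create(
      _["f_active"] = d.f_active, _["f_passive"] = d.f_passive,
      _["gxb_t"] = d.gxb_t * 1000.0, _["sovf_thick"] = d.sovf_thick,
      _["sovf_thin"] = d.sovf_thin, _["permtot"] = d.permtot);
}

// [[Rcpp::export]]
NumericVector rice_init_cpp(NumericVector params, double ca_dia) {
  RiceParams p = rice_params_from(params);
  NumericVector y(RICE_NSTATE);
  rice_init_state(REAL(y), p, ca_dia);
  return y;
}
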
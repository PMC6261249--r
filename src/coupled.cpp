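#include "rice.h"
#include <vector>

using namespace Rcpp;

// Closed-loop lumped circulation coupled to N-segment ventricular walls.
// Each segment is a Rice-type myofilament unit driven by a delayed Ca2+
// transient; cavity pressure = passive exponential P-V curve plus wall-
// tension term scaled by a thick-walled-sphere geometry factor.
// Units: mL, mmHg, ms; flows mL/ms.

static inline double lookup_ca(double t, double bcl,
                               const std::vector<double>& ct,
                               const std::vector<double>& cv) {
  double tm = t - bcl * std::floor(t / bcl);
  size_t n = ct.size();
  if (tm <= ct[0]) return cv[0];
  if (tm >= ct[n - 1]) return cv[n - 1];
  size_t lo = 0;
  double step = ct[1] - ct[0];
  lo = (size_t)((tm - ct[0]) / step);
  if (lo >= n - 1) lo = n - 2;
  while (lo > 0 && ct[lo] > tm) --lo;
  while (lo < n - 2 && ct[lo + 1] < tm) ++lo;
  double w = (tm - ct[lo]) / (ct[lo + 1] - ct[lo]);
  return cv[lo] * (1.0 - w) + cv[lo + 1] * w;
}

// [[Rcpp::export]]
List coupled_run_cpp(NumericVector rice_params, NumericVector seg_delay,
                     NumericVector seg_weight, IntegerVector seg_ventricle,
                     NumericVector ca_time, NumericVector ca_value,
                     NumericVector circ, double lvad_rate,  // mL/ms
                     double bcl, int n_beats, double dt, double sample_dt,
                     double k_coup_lv, double k_coup_rv) {
  RiceParams rp = rice_params_from(rice_params);
  const int nseg = seg_delay.size();
  std::vector<double> ct(ca_time.begin(), ca_time.end());
  std::vector<double> cv(ca_value.begin(), ca_value.end());
  double ca_dia = cv.empty() ? 0.1 : cv[0];

  std::vector<std::vector<double> > seg(nseg,
                                        std::vector<double>(RICE_NSTATE));
  for (int s = 0; s < nseg; ++s) rice_init_state(seg[s].data(), rp, ca_dia);

  // circulation parameters
  const double r_mi = circ["r_mi"], r_ao = circ["r_ao"], r_sa = circ["r_sa"],
               r_sv = circ["r_sv"], r_tr = circ["r_tr"], r_pu = circ["r_pu"],
               r_pa = circ["r_pa"], r_pv = circ["r_pv"];
  const double c_la = circ["c_la"], c_sa = circ["c_sa"], c_sv = circ["c_sv"],
               c_ra = circ["c_ra"], c_pa = circ["c_pa"], c_pv = circ["c_pv"];
  const double v0_la = circ["v0_la"], v0_sa = circ["v0_sa"],
               v0_sv = circ["v0_sv"], v0_ra = circ["v0_ra"],
               v0_pa = circ["v0_pa"], v0_pv = circ["v0_pv"];
  const double p0_lv = circ["p0_lv"], beta_lv = circ["beta_lv"],
               v0_lv = circ["v0_lv"], c_act_lv = circ["c_act_lv"],
               vref_lv = circ["vref_lv"], vd_lv = circ["vd_lv"];
  const double p0_rv = circ["p0_rv"], beta_rv = circ["beta_rv"],
               v0_rv = circ["v0_rv"], c_act_rv = circ["c_act_rv"],
               vref_rv = circ["vref_rv"], vd_rv = circ["vd_rv"];

  double v_lv = circ["vi_lv"], v_rv = circ["vi_rv"], v_la = circ["vi_la"],
         v_sa = circ["vi_sa"], v_sv = circ["vi_sv"], v_ra = circ["vi_ra"],
         v_pa = circ["vi_pa"], v_pv = circ["vi_pv"];

  const long nsteps = (long) std::llround(bcl * n_beats / dt);
  const long sample_every = std::max(1L, (long) std::llround(sample_dt / dt));
  const long n_samp = nsteps / sample_every + 1;

  NumericVector t_o(n_samp), plv_o(n_samp), vlv_o(n_samp), prv_o(n_samp),
      vrv_o(n_samp), pla_o(n_samp), psa_o(n_samp), psv_o(n_samp),
      pra_o(n_samp), ppa_o(n_samp), ppv_o(n_samp), qmi_o(n_samp),
      qao_o(n_samp), qlvad_o(n_samp), qtr_o(n_samp), qpu_o(n_samp),
      vtot_o(n_samp);

  // per-segment traces over the final beat
  const double t_last = bcl * (n_beats - 1);
  const long n_seg_samp = (long) std::llround(bcl / sample_dt) + 1;
  NumericMatrix sl_o(n_seg_samp, nseg), tens_o(n_seg_samp, nseg),
      e_o(n_seg_samp, nseg);
  NumericVector tseg_o(n_seg_samp);

  long isamp = 0, iseg = 0;
  bool neg_volume = false;
  double t_neg = NA_REAL;

  for (long k = 0; k <= nsteps; ++k) {
    double t = k * dt;

    // wall tension per ventricle
    double tw_lv = 0.0, tw_rv = 0.0;
    std::vector<double> fact(nseg);
    for (int s = 0; s < nseg; ++s) {
      RiceDerived d = rice_derived(seg[s].data(), rp);
      fact[s] = d.f_active;
      if (seg_ventricle[s] == 0) tw_lv += seg_weight[s] * d.f_active;
      else tw_rv += seg_weight[s] * d.f_active;
    }

    // chamber pressures: exponential passive curve plus tension-scaled
    // linear ESPVR (length dependence of the pressure-generating capacity)
    double len_lv = std::max(0.0, (v_lv - vd_lv) / (vref_lv - vd_lv));
    double len_rv = std::max(0.0, (v_rv - vd_rv) / (vref_rv - vd_rv));
    double p_lv = p0_lv * (std::exp(beta_lv * (v_lv - v0_lv)) - 1.0) +
                  c_act_lv * len_lv * tw_lv;
    double p_rv = p0_rv * (std::exp(beta_rv * (v_rv - v0_rv)) - 1.0) +
                  c_act_rv * len_rv * tw_rv;

    double p_la = (v_la - v0_la) / c_la;
    double p_sa = (v_sa - v0_sa) / c_sa;
    double p_sv = (v_sv - v0_sv) / c_sv;
    double p_ra = (v_ra - v0_ra) / c_ra;
    double p_pa = (v_pa - v0_pa) / c_pa;
    double p_pv = (v_pv - v0_pv) / c_pv;

    // flows (valves are diodes)
    double q_mi = std::max(0.0, (p_la - p_lv) / r_mi);
    double q_ao = std::max(0.0, (p_lv - p_sa) / r_ao);
    double q_sa = (p_sa - p_sv) / r_sa;
    double q_sv = (p_sv - p_ra) / r_sv;
    double q_tr = std::max(0.0, (p_ra - p_rv) / r_tr);
    double q_pu = std::max(0.0, (p_rv - p_pa) / r_pu);
    double q_pa = (p_pa - p_pv) / r_pa;
    double q_pv = (p_pv - p_la) / r_pv;
    double q_lvad = lvad_rate;

    if (k % sample_every == 0 && isamp < n_samp) {
      t_o[isamp] = t; plv_o[isamp] = p_lv; vlv_o[isamp] = v_lv;
      prv_o[isamp] = p_rv; vrv_o[isamp] = v_rv; pla_o[isamp] = p_la;
      psa_o[isamp] = p_sa; psv_o[isamp] = p_sv; pra_o[isamp] = p_ra;
      ppa_o[isamp] = p_pa; ppv_o[isamp] = p_pv; qmi_o[isamp] = q_mi;
      qao_o[isamp] = q_ao; qlvad_o[isamp] = q_lvad; qtr_o[isamp] = q_tr;
      qpu_o[isamp] = q_pu;
      vtot_o[isamp] = v_lv + v_rv + v_la + v_sa + v_sv + v_ra + v_pa + v_pv;
      ++isamp;
    }
    if (k % sample_every == 0 && t >= t_last - 1e-9) {
      long row = (k - (long) std::llround(t_last / dt)) / sample_every;
      if (row >= 0 && row < n_seg_samp) {
        tseg_o[row] = t - t_last;
        for (int s = 0; s < nseg; ++s) {
          RiceDerived d = rice_derived(seg[s].data(), rp);
          sl_o(row, s) = seg[s][7];
          tens_o(row, s) = d.f_active;
          e_o(row, s) = d.gxb_t * 1000.0 * d.sovf_thick;
        }
        iseg = row + 1;
      }
    }
    if (k == nsteps) break;

    // advance compartment volumes (conservative by construction)
    v_lv += dt * (q_mi - q_ao - q_lvad);
    v_sa += dt * (q_ao + q_lvad - q_sa);
    v_sv += dt * (q_sa - q_sv);
    v_ra += dt * (q_sv - q_tr);
    v_rv += dt * (q_tr - q_pu);
    v_pa += dt * (q_pu - q_pa);
    v_pv += dt * (q_pa - q_pv);
    v_la += dt * (q_pv - q_mi);
    if (v_lv < 0.0 || v_rv < 0.0 || v_la < 0.0 || v_ra < 0.0) {
      neg_volume = true; t_neg = t;
      break;
    }

    // advance myofilament units; segments of a ventricle are coupled by a
    // mean-field elastic constraint: early-shortening segments prestretch
    // the still-passive ones (ext load positive = stretching)
    double slbar_lv = 0.0, slbar_rv = 0.0;
    for (int s = 0; s < nseg; ++s) {
      if (seg_ventricle[s] == 0) slbar_lv += seg_weight[s] * seg[s][7];
      else slbar_rv += seg_weight[s] * seg[s][7];
    }
    for (int s = 0; s < nseg; ++s) {
      double ca;
      if (ISNA(seg_delay[s])) {
        ca = ca_dia;  // electrically unactivated segment
      } else {
        ca = lookup_ca(t - seg_delay[s], bcl, ct, cv);
      }
      double ext = (seg_ventricle[s] == 0)
                       ? k_coup_lv * (seg[s][7] - slbar_lv)
                       : k_coup_rv * (seg[s][7] - slbar_rv);
      rice_step(seg[s].data(), ca, rp, dt, 1, ext);
    }
  }

  List out = List::create(
      _["time"] = t_o, _["p_lv"] = plv_o, _["v_lv"] = vlv_o,
      _["p_rv"] = prv_o, _["v_rv"] = vrv_o, _["p_la"] = pla_o,
      _["p_sa"] = psa_o, _["p_sv"] = psv_o, _["p_ra"] = pra_o,
      _["p_pa"] = ppa_o, _["p_pv"] = ppv_o, _["q_mi"] = qmi_o,
      _["q_ao"] = qao_o, _["q_lvad"] = qlvad_o, _["q_tr"] = qtr_o,
      _["q_pu"] = qpu_o, _["v_total"] = vtot_o);
  out["seg_time"] = tseg_o;
  out["seg_sl"] = sl_o;
  out["seg_tension"] = tens_o;
  out["seg_e_rate"] = e_o;
  out["neg_volume"] = neg_volume;
  out["t_neg"] = t_neg;
  return out;
}
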
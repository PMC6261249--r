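#ifndef CARDIOEM_TNNP_H
#define CARDIOEM_TNNP_H

#include <Rcpp.h>
#include <cmath>

// ten Tusscher-Noble-Noble-Panfilov (2004) human ventricular myocyte model.
// State layout (17):
//  0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 fca, 7 r, 8 s, 9 xr1, 10 xr2, 11 xs,
// 12 g, 13 ca_i, 14 ca_sr, 15 na_i, 16 k_i
// Units: mV, ms, mM; currents in pA/pF.

#define TNNP_NSTATE 17

struct TnnpParams {
  // maximal conductances / pump maxima (pA/pF based units)
  double g_na, g_k1, g_to, g_kr, g_ks, g_cal, k_naca, p_nak;
  double g_pca, g_pk, g_bca, g_bna;
  // membrane capacitance per unit area (Eq 1 divisor; currents are pA/pF)
  double cm;
  // capacitance used in the concentration material balances (uF)
  double cm_ca;
  // calcium handling
  double v_leak, vmax_up, k_up, a_rel, b_rel, c_rel;
  double buf_c, k_bufc, buf_sr, k_bufsr, v_c, v_sr;
  // environment / constants
  double rgas, temp, faraday;
  double na_o, k_o, ca_o, p_kna;
  double km_k, km_na, km_nai, km_ca, k_sat, alpha_naca, gamma_naca, kp_ca;
  // s-gate kinetics variant: 0 = endo, 1 = mid/epi
  int s_epi_kinetics;
};

struct TnnpCurrents {
  double i_na, i_k1, i_to, i_kr, i_ks, i_cal, i_naca, i_nak;
  double i_pca, i_pk, i_bca, i_bna, i_ion;
};

struct TnnpFluxes {
  double i_leak, i_up, i_rel;
  double dca_i_total, dca_sr_total;
  double ca_i_bufc, ca_sr_bufsr;
};

TnnpParams tnnp_params_from(const Rcpp::NumericVector& p);
TnnpCurrents tnnp_currents(const double* y, const TnnpParams& p);
TnnpFluxes tnnp_fluxes(const double* y, const TnnpParams& p,
                       const TnnpCurrents& cur);
// Full right-hand side (pure ODE form, freeze rules encoded as zero rates).
void tnnp_rhs(const double* y, const TnnpParams& p, double istim, double* dy);
// One Rush-Larsen / forward-Euler step of size dt with voltage-change-capped
// substepping (dv_max, mV per substep).
void tnnp_step(double* y, const TnnpParams& p, double istim, double dt,
               double dv_max);

#endif
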
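#ifndef CARDIOEM_RICE_H
#define CARDIOEM_RICE_H

#include <Rcpp.h>
#include <cmath>

// Rice-type approximate cross-bridge cycling / thin-filament activation model
// driven by a prescribed Ca2+ transient (uM), with the series-elastic
// sarcomere-length ODE and ATP economy (E = gxbT * SOVFThick).
// State layout (9):
//  0 trpn_ca_l, 1 trpn_ca_h, 2 n_nox, 3 xb_prer, 4 xb_postr,
//  5 x_xb_prer, 6 x_xb_postr, 7 sl, 8 intf
// Units: ms, uM, um; forces normalized to maximal isometric tension.

#define RICE_NSTATE 9

struct RiceParams {
  double kon, koffl, koffh, perm50, nperm, kn_p, kp_n;
  double fapp, gapp, gslmod, hf, hfmdc, hb, hbmdc, gxb, sigmap, sigman;
  double xbmodsp;
  double qkon, qkoff, qkn_p, qkp_n, qfapp, qgapp, qhf, qhb, qgxb, tmpc;
  double sl_max, sl_min, len_thin, len_thick, len_hbare, x_0, x_psi;
  double pcon_t, pexp_t, sl_rest, pcon_c, pexp_c, sl_c, passive_scale;
  double sl0, kse, visc, mass;
  // derived at construction
  double kon_t, koffl_t, koffh_t, kn_p_t, kp_n_t;
  double fapp_t, gapp_base_t, hf_base_t, hb_base_t, gxb_base_t;
  double ss_xb_prer, ss_xb_postr, fnorm;
};

struct RiceDerived {
  double sovf_thick, sovf_thin;
  double f_active;   // normalized active tension (>= 0 in normal operation)
  double f_passive;  // signed: positive resists stretch (SL > rest length)
  double gxb_t;      // strain-adjusted detachment rate (1/ms)
  double permtot;
};

RiceParams rice_params_from(const Rcpp::NumericVector& p);
RiceDerived rice_derived(const double* y, const RiceParams& p);
// advance by dt; ca in uM; mode 0 = isometric (dSL/dt = 0), 1 = isotonic;
// ext_load: extra stretching load entering the afterload balance
void rice_step(double* y, double ca, const RiceParams& p, double dt, int mode,
               double ext_load);
void rice_init_state(double* y, const RiceParams& p, double ca_dia);

#endif
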
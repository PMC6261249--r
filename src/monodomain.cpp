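#include "tnnp.h"
#include <vector>

using namespace Rcpp;

// y = (I - dt*L) x for a sparse symmetric L in CSC arrays
static void apply_op(const int* lp, const int* li, const double* lx, int n,
                     double dt, const double* x, double* y) {
  for (int i = 0; i < n; ++i) y[i] = x[i];
  for (int col = 0; col < n; ++col) {
    double xc = x[col];
    for (int k = lp[col]; k < lp[col + 1]; ++k) {
      y[li[k]] -= dt * lx[k] * xc;
    }
  }
}

// Jacobi-preconditioned conjugate gradients for (I - dt*L) x = b
static int cg_solve(const int* lp, const int* li, const double* lx, int n,
                    double dt, const double* diag_l, const double* b,
                    double* x, double tol, int maxit,
                    std::vector<double>& r, std::vector<double>& z,
                    std::vector<double>& pv, std::vector<double>& ap) {
  apply_op(lp, li, lx, n, dt, x, r.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - r[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = r[i] / (1.0 - dt * diag_l[i]);
    pv[i] = z[i];
    rz += r[i] * z[i];
  }
  for (int it = 0; it < maxit; ++it) {
    double rn = 0.0;
    for (int i = 0; i < n; ++i) rn += r[i] * r[i];
    if (std::sqrt(rn) <= tol * bnorm) return it;
    apply_op(lp, li, lx, n, dt, pv.data(), ap.data());
    double pap = 0.0;
    for (int i = 0; i < n; ++i) pap += pv[i] * ap[i];
    double alpha = rz / pap;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * pv[i];
      r[i] -= alpha * ap[i];
    }
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = r[i] / (1.0 - dt * diag_l[i]);
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) pv[i] = z[i] + beta * pv[i];
  }
  return maxit;
}

// Operator-split monodomain: Rush-Larsen reaction step per node, then
// backward-Euler diffusion solved by preconditioned CG on (I - dt*L).
// laplacian: dgCMatrix slots of the conduction operator (1/ms units).
// stimuli: matrix with columns node (1-based), t_start, duration, amplitude.
// [[Rcpp::export]]
List monodomain_cpp(NumericMatrix state0, IntegerVector cell_type,
                    NumericVector params_endo, NumericVector params_mid,
                    NumericVector params_epi, IntegerVector lap_p,
                    IntegerVector lap_i, NumericVector lap_x,
                    NumericMatrix stimuli, double duration, double dt,
                    double dv_max, double eat_threshold,
                    IntegerVector probe_nodes, double sample_dt) {
  const int n = state0.ncol();
  const int ns = state0.nrow();
  if (ns != TNNP_NSTATE) stop("state matrix must have 17 rows");

  TnnpParams pars[3] = {tnnp_params_from(params_endo),
                        tnnp_params_from(params_mid),
                        tnnp_params_from(params_epi)};

  // node-major state copy
  std::vector<double> y((size_t) n * TNNP_NSTATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < TNNP_NSTATE; ++s)
      y[(size_t) i * TNNP_NSTATE + s] = state0(s, i);

  // diagonal of L
  std::vector<double> diag_l(n, 0.0);
  for (int col = 0; col < n; ++col)
    for (int k = lap_p[col]; k < lap_p[col + 1]; ++k)
      if (lap_i[k] == col) diag_l[col] = lap_x[k];

  std::vector<double> v(n), vprev(n), istim(n, 0.0);
  for (int i = 0; i < n; ++i) v[i] = y[(size_t) i * TNNP_NSTATE];
  std::vector<double> r(n), z(n), pv(n), ap(n), rhs(n);

  std::vector<double> eat(n, NA_REAL);

  const long nsteps = (long) std::llround(duration / dt);
  const long sample_every = std::max(1L, (long) std::llround(sample_dt / dt));
  const int npr = probe_nodes.size();
  const long n_samp = nsteps / sample_every + 1;
  NumericMatrix probe_v(npr > 0 ? n_samp : 0, npr);
  NumericVector probe_t(npr > 0 ? n_samp : 0);

  const int nstim = stimuli.nrow();
  long isamp = 0;
  bool unstable = false;
  double t_fail = NA_REAL;

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (npr > 0 && step % sample_every == 0 && isamp < n_samp) {
      probe_t[isamp] = t;
      for (int q = 0; q < npr; ++q)
        probe_v(isamp, q) = v[probe_nodes[q] - 1];
      ++isamp;
    }
    if (step == nsteps) break;

    // stimulus currents for this step
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int s = 0; s < nstim; ++s) {
      double t0 = stimuli(s, 1), du = stimuli(s, 2);
      if (t >= t0 && t < t0 + du) {
        int node = (int) stimuli(s, 0) - 1;
        istim[node] += stimuli(s, 3);
      }
    }

    for (int i = 0; i < n; ++i) vprev[i] = v[i];

    // reaction
    for (int i = 0; i < n; ++i) {
      double* yi = &y[(size_t) i * TNNP_NSTATE];
      yi[0] = v[i];
      tnnp_step(yi, pars[cell_type[i]], istim[i], dt, dv_max);
      v[i] = yi[0];
    }

    // diffusion (implicit)
    std::copy(v.begin(), v.end(), rhs.begin());
    cg_solve(lap_p.begin(), lap_i.begin(), REAL(lap_x), n, dt,
             diag_l.data(), rhs.data(), v.data(), 1e-8, 300, r, z, pv, ap);

    for (int i = 0; i < n; ++i) {
      if (!R_finite(v[i])) { unstable = true; t_fail = t; break; }
      y[(size_t) i * TNNP_NSTATE] = v[i];
      if (ISNA(eat[i]) && vprev[i] < eat_threshold && v[i] >= eat_threshold) {
        eat[i] = t + dt * (eat_threshold - vprev[i]) / (v[i] - vprev[i]);
      }
    }
    if (unstable) break;
  }

  NumericMatrix final_state(TNNP_NSTATE, n);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < TNNP_NSTATE; ++s)
      final_state(s, i) = y[(size_t) i * TNNP_NSTATE + s];

  return List::create(
      _["eat"] = NumericVector(eat.begin(), eat.end()),
      _["probe_time"] = probe_t, _["probe_v"] = probe_v,
      _["final_state"] = final_state, _["unstable"] = unstable,
      _["t_fail"] = t_fail);
}
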
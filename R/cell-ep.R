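#' Ventricular myocyte parameter set
#'
#' Parameters of the human ventricular membrane model (ten Tusscher-type 2004
#' formulation) with transmural variants: endocardial, midmyocardial and
#' epicardial cells differ in the transient-outward conductance, the slow
#' delayed-rectifier conductance and the inactivation kinetics of the
#' transient-outward current. Currents are expressed per unit membrane
#' capacitance (pA/pF), so the membrane capacitance `cm` entering the
#' voltage equation defaults to 1; `cm_ca` is the cell capacitance (uF) used
#' in the ionic material balances.
#'
#' @param cell_type `"endo"`, `"mid"` or `"epi"`
#' @param overrides named list of parameter overrides
#' @return named numeric vector of class `cell_params` with attribute
#'   `cell_type`
#' @export
cell_params <- function(cell_type = c("endo", "mid", "epi"),
                        overrides = list()) {
  cell_type <- match.arg(cell_type)
  p <- c(
    g_na = 14.838, g_k1 = 5.405,
    g_to = if (cell_type == "endo") 0.073 else 0.294,
    g_kr = 0.096,
    g_ks = if (cell_type == "mid") 0.062 else 0.245,
    g_cal = 0.000175, k_naca = 1000, p_nak = 1.362, g_pca = 0.825,
    g_pk = 0.0146, g_bca = 0.000592, g_bna = 0.00029,
    cm = 1, cm_ca = 0.185,
    v_leak = 8e-5, vmax_up = 4.25e-4, k_up = 2.5e-4,
    a_rel = 0.016464, b_rel = 0.25, c_rel = 0.008232,
    buf_c = 0.15, k_bufc = 0.001, buf_sr = 10, k_bufsr = 0.3,
    v_c = 0.016404, v_sr = 0.001094,
    rgas = 8314.472, temp = 310, faraday = 96485.3415,
    na_o = 140, k_o = 5.4, ca_o = 2, p_kna = 0.03,
    km_k = 1, km_na = 40, km_nai = 87.5, km_ca = 1.38, k_sat = 0.1,
    alpha_naca = 2.5, gamma_naca = 0.35, kp_ca = 5e-4,
    s_epi_kinetics = if (cell_type == "endo") 0 else 1)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  nonneg <- c("g_na", "g_k1", "g_to", "g_kr", "g_ks", "g_cal", "k_naca",
              "p_nak", "g_pca", "g_pk", "g_bca", "g_bna", "v_leak",
              "vmax_up", "a_rel", "c_rel", "buf_c", "buf_sr", "v_c", "v_sr")
  if (any(p[nonneg] < 0)) stop("conductances, pump maxima, volumes and buffer
 capacities must be non-negative")
  if (p["cm"] <= 0) stop("cm must be positive")
  structure(p, cell_type = cell_type, class = "cell_params")
}

#' Resting myocyte state
#'
#' The standard resting initial condition of the 2004 human ventricular
#' model: membrane voltage, gating variables (including the SR-release gates
#' `d` and `g`) and intracellular concentrations.
#'
#' @param overrides named list of state overrides
#' @return named numeric vector of class `cell_state`
#' @export
cell_state <- function(overrides = list()) {
  y <- c(V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, fca = 1,
         r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0, g = 1,
         ca_i = 2e-4, ca_sr = 0.2, na_i = 11.6, k_i = 138.3)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(y))
    if (length(bad)) stop("unknown state field(s): ",
                          paste(bad, collapse = ", "))
    y[names(overrides)] <- unlist(overrides)
  }
  structure(y, class = "cell_state")
}

cell_state_check <- function(state) {
  nm <- names(state)
  bad <- nm[!is.finite(state)]
  if (length(bad)) stop("non-finite state value in field(s): ",
                        paste(bad, collapse = ", "))
  gates <- c("m", "h", "j", "d", "f", "fca", "r", "s", "xr1", "xr2", "xs",
             "g")
  out <- gates[state[gates] < 0 | state[gates] > 1]
  if (length(out)) stop("gate(s) outside [0, 1]: ", paste(out, collapse = ", "))
  conc <- c("ca_i", "ca_sr", "na_i", "k_i")
  neg <- conc[state[conc] <= 0]
  if (length(neg)) stop("non-positive concentration(s): ",
                        paste(neg, collapse = ", "))
  invisible(TRUE)
}

#' Transmembrane ionic currents
#'
#' Evaluates the twelve membrane currents of the ventricular model and their
#' sum `i_ion` (the total ionic current of the voltage equation).
#'
#' @param state a [cell_state()]
#' @param params a [cell_params()]
#' @return named numeric vector with the twelve currents (pA/pF) and `i_ion`
#' @export
ionic_currents <- function(state, params) {
  cell_state_check(state)
  tnnp_currents_cpp(unclass(state), unclass(params))
}

#' Sarcoplasmic-reticulum calcium fluxes
#'
#' Leak, SERCA uptake and calcium-induced release fluxes, the buffered
#' calcium fractions and the total-calcium time derivatives of the cytosolic
#' and SR compartments.
#'
#' @param state a [cell_state()]
#' @param params a [cell_params()]
#' @return list with `i_leak`, `i_up`, `i_rel` (mM/ms), `dca_i_total`,
#'   `dca_sr_total`, `ca_i_bufc`, `ca_sr_bufsr`
#' @export
calcium_fluxes <- function(state, params) {
  cell_state_check(state)
  if (state["ca_i"] <= 0 || state["ca_sr"] <= 0) {
    stop("calcium concentrations must be positive")
  }
  tnnp_fluxes_cpp(unclass(state), unclass(params))
}

#' Time derivatives of the myocyte state
#'
#' The full right-hand side of the cell model in pure ODE form; intended for
#' cross-checking the fixed-step integrator against a general-purpose stiff
#' solver.
#'
#' @inheritParams ionic_currents
#' @param i_stim applied stimulus current (pA/pF; inward negative)
#' @return named numeric vector of time derivatives
#' @export
cell_derivatives <- function(state, params, i_stim = 0) {
  d <- tnnp_rhs_cpp(unclass(state), unclass(params), i_stim)
  names(d) <- names(cell_state())
  d
}

#' Advance a myocyte by one time step
#'
#' Rush-Larsen exponential updates for the gating variables and forward
#' updates for voltage and concentrations, with voltage-change-capped
#' substepping for accuracy during the upstroke.
#'
#' @inheritParams cell_derivatives
#' @param dt step size (ms), positive
#' @param dv_max largest voltage change allowed per internal substep (mV)
#' @return the advanced `cell_state`
#' @export
step_cell <- function(state, params, i_stim = 0, dt = 0.02, dv_max = 0.2) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  cell_state_check(state)
  y <- tnnp_step_cpp(unclass(state), unclass(params), i_stim, dt, dv_max)
  names(y) <- names(state)
  out <- structure(y, class = "cell_state")
  tryCatch(cell_state_check(out),
           error = function(e) stop("integration instability: ",
                                    conditionMessage(e)))
  out
}

#' Pacing protocol
#'
#' @param bcl basic cycle length (ms)
#' @param stim_amp stimulus amplitude (pA/pF; inward negative). The default
#'   is about twice the diastolic threshold.
#' @param stim_dur stimulus duration (ms)
#' @param n_beats number of paced beats
#' @param dt integration step (ms)
#' @param dv_max voltage-change cap per substep (mV)
#' @return list of class `pacing_protocol`
#' @export
pacing_protocol <- function(bcl = 600, stim_amp = -52, stim_dur = 1,
                            n_beats = 20, dt = 0.02, dv_max = 0.2) {
  stopifnot(bcl > stim_dur, stim_dur > 0, n_beats >= 0, dt > 0)
  structure(list(bcl = bcl, stim_amp = stim_amp, stim_dur = stim_dur,
                 n_beats = n_beats, dt = dt, dv_max = dv_max),
            class = "pacing_protocol")
}

#' Run a paced single-cell simulation
#'
#' Paces the myocyte at the protocol's basic cycle length and returns sampled
#' traces of voltage, calcium and SR fluxes for every beat, per-beat
#' summaries, and a steady-state flag (relative change of peak Ca and APD90
#' between the last two beats below 1 percent). The final beat is the
#' analysis beat.
#'
#' @param params a [cell_params()]
#' @param protocol a [pacing_protocol()]
#' @param state0 initial state (defaults to the resting state)
#' @param sample_dt trace sampling interval (ms)
#' @return list with `trace` (data.frame: time, v, ca_i, ca_sr, na_i, k_i,
#'   i_leak, i_up, i_rel, beat), `beats` (per-beat peak voltage, peak Ca,
#'   APD90), `steady`, `captured`, `final_state`, `analysis_beat`
#' @export
run_paced_cell <- function(params, protocol = pacing_protocol(),
                           state0 = cell_state(), sample_dt = 1) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  if (protocol$n_beats == 0) {
    return(list(trace = data.frame(time = numeric(0), v = numeric(0),
                                   ca_i = numeric(0), ca_sr = numeric(0),
                                   na_i = numeric(0), k_i = numeric(0),
                                   i_leak = numeric(0), i_up = numeric(0),
                                   i_rel = numeric(0), beat = integer(0)),
                beats = data.frame(beat = integer(0), peak_v = numeric(0),
                                   peak_ca_i = numeric(0), apd90 = numeric(0)),
                steady = NA, captured = logical(0),
                final_state = state0, analysis_beat = NA_integer_))
  }
  res <- run_paced_cell_cpp(unclass(state0), unclass(params),
                            protocol$bcl, protocol$n_beats, protocol$dt,
                            protocol$stim_amp, protocol$stim_dur, sample_dt,
                            protocol$dv_max)
  trace <- data.frame(time = res$time, v = res$v, ca_i = res$ca_i,
                      ca_sr = res$ca_sr, na_i = res$na_i, k_i = res$k_i,
                      i_leak = res$i_leak, i_up = res$i_up,
                      i_rel = res$i_rel, beat = res$beat)
  apd <- vapply(seq_len(protocol$n_beats), function(b) {
    tr <- trace[trace$beat == b, ]
    if (nrow(tr) < 3) return(NA_real_)
    vmax <- max(tr$v); vrest <- tr$v[1]
    if (vmax - vrest < 10) return(NA_real_)
    thr <- vmax - 0.9 * (vmax - vrest)
    above <- which(tr$v > thr)
    tr$time[max(above)] - tr$time[min(above)]
  }, numeric(1))
  beats <- data.frame(beat = seq_len(protocol$n_beats), peak_v = res$peak_v,
                      peak_ca_i = res$peak_ca_i, apd90 = apd)
  captured <- res$peak_v > 0
  if (!all(captured)) {
    warning("failure to capture on beat(s): ",
            paste(which(!captured), collapse = ", "))
  }
  steady <- NA
  nb <- protocol$n_beats
  if (nb >= 2 && all(is.finite(apd[(nb - 1):nb]))) {
    d_ca <- abs(res$peak_ca_i[nb] - res$peak_ca_i[nb - 1]) /
      res$peak_ca_i[nb - 1]
    d_apd <- abs(apd[nb] - apd[nb - 1]) / apd[nb - 1]
    steady <- (d_ca < 0.01) && (d_apd < 0.01)
  }
  fs <- res$final_state
  names(fs) <- names(cell_state())
  list(trace = trace, beats = beats, steady = steady, captured = captured,
       final_state = structure(fs, class = "cell_state"),
       analysis_beat = nb)
}
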
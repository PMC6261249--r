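#' Lumped circulation parameters
#'
#' Closed-loop circulation: left/right atria as passive compliance chambers,
#' systemic and pulmonary arterial/venous compartments, diode valves
#' (mitral, aortic, tricuspid, pulmonary), and reduced-order ventricular
#' chambers whose pressure combines an exponential passive P-V curve with a
#' wall-tension term scaled by a thick-walled-sphere geometry factor.
#' The shipped defaults are tuned so that the no-LVAD failing baseline at a
#' basic cycle length of 600 ms lands near EDV 88 mL, EF 38 percent and CO
#' 3.4 L/min; all values can be overridden.
#'
#' Units: pressures mmHg, volumes mL, time ms; resistances mmHg ms/mL,
#' compliances mL/mmHg.
#'
#' @param overrides named list of parameter overrides
#' @return named numeric vector of class `circulation_params`
#' @export
circulation_params <- function(overrides = list()) {
  p <- c(
    # valve and vascular resistances
    r_mi = 4, r_ao = 8, r_sa = 2300, r_sv = 60, r_tr = 4, r_pu = 6,
    r_pa = 120, r_pv = 60,
    # compliances
    c_la = 4, c_sa = 0.85, c_sv = 30, c_ra = 5, c_pa = 5, c_pv = 8,
    # unstressed volumes
    v0_la = 0, v0_sa = 0, v0_sv = 0, v0_ra = 0, v0_pa = 0, v0_pv = 0,
    # LV chamber (passive curve is pre-stiffening; the heart-failure
    # passive scaling of the myofilament parameters multiplies p0)
    p0_lv = 0.35, beta_lv = 0.042, v0_lv = 40, c_act_lv = 700,
    vref_lv = 88, vd_lv = 30,
    # RV chamber
    p0_rv = 0.12, beta_rv = 0.04, v0_rv = 40, c_act_rv = 85,
    vref_rv = 90, vd_rv = 10,
    # initial volumes (state)
    vi_lv = 88, vi_rv = 90, vi_la = 32, vi_sa = 85, vi_sv = 380,
    vi_ra = 20, vi_pa = 75, vi_pv = 64)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  rc <- grep("^(r|c)_", names(p), value = TRUE)
  if (any(p[rc] <= 0)) stop("resistances and compliances must be positive")
  structure(p, class = "circulation_params")
}

#' LVAD configuration
#'
#' Continuous-flow assist device modelled as a constant-flow generator
#' withdrawing blood from the LV and delivering it to the systemic artery.
#'
#' @param enabled logical
#' @param flow_lpm mean flow rate (L/min), >= 0
#' @return list of class `lvad_params`
#' @export
lvad_params <- function(enabled = FALSE, flow_lpm = 3) {
  stopifnot(is.logical(enabled), flow_lpm >= 0)
  structure(list(enabled = enabled, flow_lpm = flow_lpm),
            class = "lvad_params")
}

#' Instantaneous LVAD flow
#'
#' Constant-flow device: returns the configured mean rate at every time when
#' enabled, 0 when disabled.
#'
#' @param lvad an [lvad_params()]
#' @param t time(s) (ms); accepted for interface symmetry
#' @return flow (L/min), same length as `t`
#' @export
lvad_flow <- function(lvad, t = 0) {
  stopifnot(inherits(lvad, "lvad_params"))
  rep(if (lvad$enabled) lvad$flow_lpm else 0, length(t))
}

#' Diode valve flow
#'
#' Ohmic flow `(p_upstream - p_downstream)/R` when the gradient is forward,
#' zero otherwise.
#'
#' @param p_upstream,p_downstream pressures (mmHg)
#' @param r valve resistance (mmHg ms/mL), positive
#' @return non-negative flow (mL/ms)
#' @export
valve_flow <- function(p_upstream, p_downstream, r) {
  if (any(r <= 0)) stop("valve resistance must be positive")
  pmax(0, (p_upstream - p_downstream) / r)
}

#' Circulation state vector
#'
#' @param params a [circulation_params()]; initial volumes are taken from
#'   its `vi_*` entries
#' @return named numeric vector of compartment volumes (mL)
#' @export
circulation_state <- function(params = circulation_params()) {
  v <- unclass(params)[c("vi_lv", "vi_rv", "vi_la", "vi_sa", "vi_sv",
                         "vi_ra", "vi_pa", "vi_pv")]
  names(v) <- sub("^vi_", "v_", names(v))
  v
}

#' Compartment pressures and flows
#'
#' Evaluates all compartment pressures, valve states and flows of the
#' closed loop for a given state and externally supplied ventricular
#' pressures.
#'
#' @param state volume state vector (see [circulation_state()])
#' @param params a [circulation_params()]
#' @param p_lv,p_rv ventricular pressures (mmHg) from the coupled
#'   ventricular model
#' @param lvad an [lvad_params()]
#' @return list with `pressures`, `flows` (mL/ms), `valves` (open flags) and
#'   `dvolume` (mL/ms per compartment)
#' @export
circulation_derivs <- function(state, params, p_lv, p_rv,
                               lvad = lvad_params()) {
  p <- unclass(params)
  pr <- c(la = (state["v_la"] - p["v0_la"]) / p["c_la"],
          sa = (state["v_sa"] - p["v0_sa"]) / p["c_sa"],
          sv = (state["v_sv"] - p["v0_sv"]) / p["c_sv"],
          ra = (state["v_ra"] - p["v0_ra"]) / p["c_ra"],
          pa = (state["v_pa"] - p["v0_pa"]) / p["c_pa"],
          pv = (state["v_pv"] - p["v0_pv"]) / p["c_pv"])
  names(pr) <- c("la", "sa", "sv", "ra", "pa", "pv")
  q_mi <- valve_flow(pr["la"], p_lv, p["r_mi"])
  q_ao <- valve_flow(p_lv, pr["sa"], p["r_ao"])
  q_sa <- (pr["sa"] - pr["sv"]) / p["r_sa"]
  q_sv <- (pr["sv"] - pr["ra"]) / p["r_sv"]
  q_tr <- valve_flow(pr["ra"], p_rv, p["r_tr"])
  q_pu <- valve_flow(p_rv, pr["pa"], p["r_pu"])
  q_pa <- (pr["pa"] - pr["pv"]) / p["r_pa"]
  q_pv <- (pr["pv"] - pr["la"]) / p["r_pv"]
  q_lvad <- lvad_flow(lvad) * 1000 / 60000  # L/min -> mL/ms
  flows <- c(q_mi = unname(q_mi), q_ao = unname(q_ao), q_sa = unname(q_sa),
             q_sv = unname(q_sv), q_tr = unname(q_tr), q_pu = unname(q_pu),
             q_pa = unname(q_pa), q_pv = unname(q_pv),
             q_lvad = unname(q_lvad))
  dv <- c(v_lv = unname(q_mi - q_ao - q_lvad),
          v_rv = unname(q_tr - q_pu),
          v_la = unname(q_pv - q_mi),
          v_sa = unname(q_ao + q_lvad - q_sa),
          v_sv = unname(q_sa - q_sv),
          v_ra = unname(q_sv - q_tr),
          v_pa = unname(q_pu - q_pa),
          v_pv = unname(q_pa - q_pv))
  list(pressures = pr, flows = flows,
       valves = c(mitral = unname(q_mi > 0), aortic = unname(q_ao > 0),
                  tricuspid = unname(q_tr > 0), pulmonary = unname(q_pu > 0)),
       dvolume = dv)
}

#' Advance the circulation by one step
#'
#' Forward update of the compartment volumes; conservative by construction
#' (every flow leaves one compartment and enters another).
#'
#' @inheritParams circulation_derivs
#' @param dt step (ms)
#' @return updated state vector
#' @export
circulation_step <- function(state, params, p_lv, p_rv,
                             lvad = lvad_params(), dt = 0.1) {
  stopifnot(dt > 0)
  d <- circulation_derivs(state, params, p_lv, p_rv, lvad)
  new <- state + dt * d$dvolume[names(state)]
  if (any(new < 0)) {
    stop("negative compartment volume in: ",
         paste(names(new)[new < 0], collapse = ", "))
  }
  new
}

#' Ventricular chamber pressure of the reduced-order wall model
#'
#' `P = P_passive(V) + c_act * T_wall * (V - V_d)/(V_ref - V_d)` with an
#' exponential passive curve; the linear volume factor represents the
#' length dependence of the wall's pressure-generating capacity (a linear
#' end-systolic pressure-volume relation whose slope follows the
#' instantaneous wall tension).
#'
#' @param v cavity volume (mL)
#' @param tension wall-averaged normalized active tension
#' @param params a [circulation_params()]
#' @param side `"lv"` or `"rv"`
#' @param passive_scale heart-failure stiffening multiplier on the passive
#'   curve
#' @return pressure (mmHg)
#' @export
chamber_pressure <- function(v, tension, params, side = c("lv", "rv"),
                             passive_scale = 1) {
  side <- match.arg(side)
  p <- unclass(params)
  g <- function(nm) unname(p[paste0(nm, "_", side)])
  len <- pmax(0, (v - g("vd")) / (g("vref") - g("vd")))
  unname(passive_scale * g("p0") * (exp(g("beta") * (v - g("v0"))) - 1) +
           g("c_act") * len * tension)
}

#' Pressure-volume loop metrics of the analysis beat
#'
#' EDV/ESV are the extreme LV volumes over the analysis beat, SV their
#' difference, EF omitted under LVAD support (the loop shape is altered by
#' the device), and CO the stroke volume rate without LVAD or the forward
#' aortic plus device flow with LVAD.
#'
#' @param trace data.frame with columns `time` (ms), `p_lv`, `v_lv`,
#'   `q_ao` (mL/ms) and `q_lvad` (mL/ms), covering at least the analysis
#'   beat
#' @param bcl beat duration (ms)
#' @param lvad an [lvad_params()]
#' @param beat_start start time of the analysis beat (ms); defaults to the
#'   last full beat in the trace
#' @return list of class `pv_metrics` with `edv`, `esv`, `sv` (mL), `ef`
#'   (percent, `NA` under LVAD), `co` (L/min), `peak_p_lv` (mmHg),
#'   `t_peak_p` (ms within the beat), `aortic_open_ms`
#' @export
pv_metrics <- function(trace, bcl, lvad = lvad_params(),
                       beat_start = NULL) {
  t_end <- max(trace$time)
  if (t_end - min(trace$time) < bcl) {
    stop("trace must cover at least one full beat")
  }
  if (is.null(beat_start)) beat_start <- t_end - bcl
  w <- trace$time >= beat_start - 1e-9 & trace$time <= beat_start + bcl + 1e-9
  tr <- trace[w, ]
  edv <- max(tr$v_lv); esv <- min(tr$v_lv)
  sv <- edv - esv
  hr <- 60000 / bcl
  dtv <- diff(tr$time)
  trapz <- function(x) sum(dtv * (head(x, -1) + tail(x, -1)) / 2)
  fwd <- trapz(tr$q_ao)            # mL per beat through the aortic valve
  pump <- trapz(tr$q_lvad)
  co <- if (lvad$enabled) {
    (fwd + pump) / bcl * 60000 / 1000          # L/min
  } else {
    sv * hr / 1000
  }
  ef <- if (lvad$enabled) NA_real_ else 100 * sv / edv
  ipk <- which.max(tr$p_lv)
  structure(list(
    edv = edv, esv = esv, sv = sv, ef = ef, co = co,
    peak_p_lv = tr$p_lv[ipk],
    t_peak_p = tr$time[ipk] - beat_start,
    aortic_open_ms = sum(dtv[head(tr$q_ao, -1) > 0 | tail(tr$q_ao, -1) > 0])),
    class = "pv_metrics")
}
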
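#' Myofilament (cross-bridge) parameter set
#'
#' Parameters of the Rice-type approximate cross-bridge model: thin-filament
#' Ca activation (troponin low/high-affinity pools, cooperative
#' permissiveness), a three-state cross-bridge cycle with strain-dependent
#' rates, sarcomere overlap geometry, the titin/collagen passive element and
#' the series-elastic sarcomere-length dynamics. Rates are the body-
#' temperature values; Q10 factors rescale them when `tmpc` differs from 37.
#' The species factor `xbmodsp` slows cross-bridge cycling to the large-
#' mammal range.
#'
#' @param overrides named list of parameter overrides
#' @param passive_scale multiplier on the passive-force element (heart
#'   failure stiffening uses 5)
#' @return named numeric vector of class `myofilament_params`
#' @export
myofilament_params <- function(overrides = list(), passive_scale = 1) {
  p <- c(
    # thin filament activation (ms, uM units)
    kon = 0.05, koffl = 0.25, koffh = 0.025, perm50 = 0.5, nperm = 15,
    kn_p = 0.5, kp_n = 0.05,
    # cross-bridge cycling (1/ms)
    fapp = 0.5, gapp = 0.07, gslmod = 6, hf = 2, hfmdc = 5,
    hb = 0.4, hbmdc = 0, gxb = 0.07, sigmap = 8, sigman = 1,
    xbmodsp = 0.2,
    # temperature scaling
    qkon = 1.5, qkoff = 1.3, qkn_p = 1.6, qkp_n = 1.6, qfapp = 6.25,
    qgapp = 2.5, qhf = 6.25, qhb = 6.25, qgxb = 6.25, tmpc = 37,
    # sarcomere geometry (um)
    sl_max = 2.4, sl_min = 1.4, len_thin = 1.2, len_thick = 1.65,
    len_hbare = 0.1, x_0 = 0.007, x_psi = 2,
    # passive element
    pcon_t = 0.002, pexp_t = 10, sl_rest = 1.9,
    pcon_c = 0.02, pexp_c = 70, sl_c = 2.25,
    passive_scale = passive_scale,
    # series-elastic sarcomere-length dynamics (normalized force, um, ms)
    sl0 = 2.2, kse = 4, visc = 3, mass = 50)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  if (p["sl0"] <= 0) stop("resting sarcomere length must be positive")
  if (p["visc"] <= 0 || p["mass"] <= 0) stop("viscosity and mass must be
 positive")
  if (p["passive_scale"] < 1) stop("passive_scale must be >= 1")
  structure(p, class = "myofilament_params")
}

#' Series-elastic afterload force
#'
#' `F_afterload(x) = K_SE * (x - SL0)`: the force carried by the series
#' elastic element at attachment length `x` relative to the resting
#' sarcomere length.
#'
#' @param x current length (um)
#' @param sl0 resting sarcomere length (um)
#' @param k_se series-elastic stiffness (normalized force per um), >= 0
#' @return afterload force (normalized)
#' @export
afterload_force <- function(x, sl0, k_se) {
  if (any(k_se < 0)) stop("k_se must be non-negative")
  k_se * (x - sl0)
}

#' Time integral of the net normalized force
#'
#' Trapezoidal quadrature of
#' `F_active + F_passive - F_preload - F_afterload` from time 0 to `t`.
#'
#' @param time monotone increasing time grid (ms)
#' @param f_active,f_passive,f_afterload force traces on `time`
#' @param f_preload constant preload force (or trace)
#' @param t upper limit(s) of integration (ms); defaults to the end of the
#'   trace
#' @return the integral at each requested `t`
#' @export
integral_force <- function(time, f_active, f_passive, f_preload,
                           f_afterload, t = max(time)) {
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  integrand <- f_active + f_passive - f_preload - f_afterload
  cum <- c(0, cumsum(diff(time) *
                       (head(integrand, -1) + tail(integrand, -1)) / 2))
  if (any(t < time[1] | t > time[length(time)])) {
    stop("t outside the sampled time range")
  }
  approx(time, cum, xout = t)$y
}

#' Advance the sarcomere-length state by one step
#'
#' Integrates the force-integral / sarcomere-length pair: the integral state
#' accumulates the net normalized force, and in isotonic mode the sarcomere
#' length follows
#' `dSL/dt = (Integral_Force + (SL0 - SL) * viscosity) / mass`.
#' Isometric mode holds `dSL/dt = 0`.
#'
#' @param state list with `sl` (um) and `intf` (integral-force state)
#' @param balance list with `f_active`, `f_passive`, `f_preload`,
#'   `f_afterload` (current values, signed normalized forces)
#' @param params a [myofilament_params()]
#' @param dt step (ms), positive
#' @param mode `"isometric"` or `"isotonic"`
#' @return updated state list; attribute `out_of_range` flags a sarcomere
#'   length outside the physical range
#' @export
sl_step <- function(state, balance, params, dt,
                    mode = c("isotonic", "isometric")) {
  mode <- match.arg(mode)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  intf <- state$intf + dt * (balance$f_active + balance$f_passive -
                               balance$f_preload - balance$f_afterload)
  sl <- state$sl
  out_of_range <- FALSE
  if (mode == "isotonic") {
    sl <- sl + dt * (intf + (params["sl0"] - sl) * params["visc"]) /
      params["mass"]
    if (sl < params["sl_min"] || sl > params["sl_max"]) {
      out_of_range <- TRUE
      warning("sarcomere length left the physical range")
      sl <- min(max(sl, params["sl_min"]), params["sl_max"])
    }
  }
  structure(list(sl = unname(sl), intf = unname(intf)),
            out_of_range = out_of_range)
}

#' ATP consumption rate
#'
#' The myofilament ATP consumption rate is the product of the cross-bridge
#' detachment rate and the thick-filament single-overlap fraction:
#' `E = g_xbT * SOVF_thick`.
#'
#' @param state list (or data.frame) with fields `g_xbt` (1/s) and
#'   `sovf_thick`, or a numeric `g_xbt` with `sovf_thick` as second argument
#' @param sovf_thick optional, when `state` is numeric
#' @return E (1/s)
#' @export
atp_rate <- function(state, sovf_thick = NULL) {
  if (is.numeric(state) && !is.null(sovf_thick)) {
    g <- state; s <- sovf_thick
  } else {
    g <- state$g_xbt; s <- state$sovf_thick
  }
  if (any(g < 0) || any(s < 0 | s > 1)) {
    stop("g_xbt must be >= 0 and sovf_thick in [0, 1]")
  }
  g * s
}

#' Passive myofilament force
#'
#' The titin + collagen passive element at a given sarcomere length,
#' multiplied by the configured passive scaling constant. Positive values
#' resist stretch.
#'
#' @param sl sarcomere length(s) (um)
#' @param params a [myofilament_params()]
#' @return signed passive force (normalized)
#' @export
passive_force <- function(sl, params) {
  vapply(sl, function(s) {
    y <- rice_init_cpp(unclass(params), 0.1)
    y[8] <- s
    rice_derived_cpp(y, unclass(params))$f_passive
  }, numeric(1))
}

#' Simulate myofilament twitches driven by a calcium transient
#'
#' Runs the cross-bridge model for `n_cycles` repeats of the supplied Ca
#' transient and reports tension, sarcomere length, strain
#' `(SL - SL0)/SL0` and the ATP consumption rate; the final cycle is the
#' analysis cycle.
#'
#' @param ca data.frame with columns `time` (ms) and `ca` (uM), one cycle
#' @param params a [myofilament_params()]
#' @param mode `"isometric"` or `"isotonic"`
#' @param n_cycles number of cycles (the first cycles settle the state)
#' @param dt integration step (ms)
#' @param sample_dt output sampling step (ms)
#' @return list with `trace` (data.frame) and `summary` (peak tension, time
#'   to peak within the final cycle, cycle ATP integral)
#' @export
run_twitch <- function(ca, params = myofilament_params(),
                       mode = c("isotonic", "isometric"), n_cycles = 4,
                       dt = 0.05, sample_dt = 1) {
  mode <- match.arg(mode)
  if (any(ca$ca <= 0)) stop("calcium transient must be positive")
  if (any(diff(ca$time) <= 0)) stop("time grid must be strictly increasing")
  cycle_ms <- max(ca$time)
  res <- rice_twitch_cpp(unclass(params), ca$time, ca$ca, cycle_ms,
                         n_cycles, dt, if (mode == "isotonic") 1L else 0L,
                         sample_dt)
  trace <- data.frame(time = res$time, sl = res$sl, strain = res$strain,
                      tension = res$tension, f_passive = res$f_passive,
                      e_rate = res$e_rate, gxb_t = res$gxb_t,
                      sovf_thick = res$sovf_thick, ca = res$ca,
                      cycle = res$cycle)
  last <- trace[trace$cycle == n_cycles, ]
  atp <- if (nrow(last) > 1) {
    sum(diff(last$time) * (head(last$e_rate, -1) + tail(last$e_rate, -1)) /
          2) / 1000  # E is 1/s, time in ms
  } else NA_real_
  list(trace = trace,
       summary = list(
         peak_tension = max(last$tension),
         time_to_peak = last$time[which.max(last$tension)] -
           min(last$time),
         min_strain = min(last$strain),
         cycle_atp = atp))
}
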
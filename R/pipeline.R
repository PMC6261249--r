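#' Heart-failure passive stiffening
#'
#' Multiplies the passive scaling constant of the myofilament parameter set.
#' The study conditions use factor 5 for every scenario: the baseline
#' ventricle is a failing, stiffened one.
#'
#' @param params a [myofilament_params()]
#' @param factor positive multiplier (5 for the failing ventricle)
#' @return updated parameter set
#' @export
apply_hf_stiffening <- function(params, factor = 5) {
  stopifnot(inherits(params, "myofilament_params"), factor > 0)
  params["passive_scale"] <- params["passive_scale"] * factor
  params
}

#' Map an activation map onto wall segments
#'
#' Partitions each ventricle into `n_segments` wall segments (longitudinal
#' bands times circumferential sectors) and assigns each segment the mean
#' electrical activation time of its member nodes as its mechanical
#' activation delay. Segments without any activated node are flagged and
#' excluded from averages.
#'
#' @param eat data.frame `node`, `eat` from [monodomain_simulate()]
#' @param mesh the `tissue_mesh` the map lives on
#' @param n_segments segments per ventricle (default 18 = 3 bands x 6
#'   sectors)
#' @return data.frame with `segment`, `ventricle`, `delay` (ms; `NA` when
#'   unactivated), `weight` (wall-volume fraction within the ventricle),
#'   `n_nodes`, `n_activated`
#' @export
map_activation_to_segments <- function(eat, mesh, n_segments = 18) {
  stopifnot(n_segments >= 1, nrow(eat) == mesh$n)
  n_z <- if (n_segments %% 3 == 0 && n_segments >= 6) 3L else 1L
  n_th <- n_segments / n_z
  if (n_th != floor(n_th)) stop("n_segments must be divisible by the band
 count")
  out <- list()
  for (vent in levels(mesh$ventricle)) {
    idx <- which(mesh$ventricle == vent)
    co <- mesh$lattice[idx, , drop = FALSE]
    zb <- if (n_z == 1) rep(1L, length(idx)) else {
      qs <- quantile(co[, 3], probs = seq(0, 1, length.out = n_z + 1))
      qs[1] <- -Inf; qs[n_z + 1] <- Inf
      as.integer(cut(co[, 3], qs, labels = FALSE, include.lowest = TRUE))
    }
    ctr <- colMeans(co)
    th <- atan2(co[, 2] - ctr[2], co[, 1] - ctr[1])
    tb <- if (n_th == 1) rep(1L, length(idx)) else {
      pmin(n_th, 1L + as.integer(floor((th + pi) / (2 * pi) * n_th)))
    }
    seg_id <- (zb - 1L) * n_th + tb
    for (s in seq_len(n_segments)) {
      members <- idx[seg_id == s]
      times <- eat$eat[members]
      act <- times[!is.na(times)]
      out[[length(out) + 1]] <- data.frame(
        segment = paste0(vent, "_", s), ventricle = vent,
        delay = if (length(act)) mean(act) else NA_real_,
        weight = length(members) / length(idx),
        n_nodes = length(members), n_activated = length(act))
    }
  }
  do.call(rbind, out)
}

#' Mechanical activation time from a strain trace
#'
#' MAT is the first time the shortening signal (baseline strain minus
#' strain) reaches 10 percent of its eventual maximal shortening, linearly
#' interpolated between samples. A flat trace returns `NA` (mechanically
#' unactivated).
#'
#' @param time time grid (ms)
#' @param strain strain trace on `time`
#' @param frac threshold fraction of maximal shortening
#' @param tol minimal shortening regarded as activation
#' @return MAT (ms) or `NA`
#' @export
compute_mat <- function(time, strain, frac = 0.1, tol = 1e-9) {
  stopifnot(length(time) == length(strain), all(diff(time) > 0))
  shortening <- strain[1] - strain
  smax <- max(shortening)
  if (!is.finite(smax) || smax <= tol) return(NA_real_)
  thr <- frac * smax
  above <- which(shortening >= thr)
  i <- above[1]
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  s0 <- shortening[i - 1]; s1 <- shortening[i]
  t0 + (thr - s0) / (s1 - s0) * (t1 - t0)
}

#' Electromechanical delay map
#'
#' `EMD = MAT - EAT` element-wise over the sites present in both maps;
#' sites missing from either map are excluded and counted.
#'
#' @param mat data.frame `segment`, `mat`
#' @param eat data.frame `segment`, `eat`
#' @return list with `map` (data.frame `segment`, `mat`, `eat`, `emd`),
#'   `mean_emd`, `mean_mat`, `mean_eat`, `n_excluded`
#' @export
compute_emd <- function(mat, eat) {
  m <- merge(mat, eat, by = "segment")
  ok <- !is.na(m$mat) & !is.na(m$eat)
  n_excluded <- nrow(mat) + nrow(eat) - 2 * sum(ok)
  m <- m[ok, ]
  m$emd <- m$mat - m$eat
  list(map = m[, c("segment", "mat", "eat", "emd")],
       mean_emd = mean(m$emd), mean_mat = mean(m$mat),
       mean_eat = mean(m$eat), n_excluded = n_excluded)
}

#' Cycle ATP consumption of the segmental wall model
#'
#' Wall-volume-weighted sum over segments of the time integral of the ATP
#' consumption rate over the beat.
#'
#' @param time sample times over the beat (ms)
#' @param e_rates matrix of per-segment ATP rates (1/s), one column per
#'   segment
#' @param weights wall-volume weights, one per segment
#' @return cycle ATP (dimensionless: rate integrated over the cycle)
#' @export
total_atp <- function(time, e_rates, weights) {
  e_rates <- as.matrix(e_rates)
  if (ncol(e_rates) != length(weights)) {
    stop("one weight per segment trace required; missing trace for segment ",
         which(is.na(match(seq_along(weights), seq_len(ncol(e_rates)))))[1])
  }
  dtv <- diff(time)
  per_seg <- vapply(seq_len(ncol(e_rates)), function(s) {
    x <- e_rates[, s]
    sum(dtv * (head(x, -1) + tail(x, -1)) / 2) / 1000
  }, numeric(1))
  sum(weights * per_seg)
}

#' Study setup: fixtures, calibration and shared inputs
#'
#' Builds the synthetic geometry and Purkinje network, calibrates the
#' conduction coefficient on a cable of matching lattice spacing, and
#' derives the steady-state calcium transient driving the myofilament
#' segments from the paced endocardial cell model.
#'
#' @param seed integer seed fixing all fixture randomness
#' @param target_nodes mesh resolution
#' @param bcl basic cycle length (ms)
#' @param target_cv myocardial conduction velocity to calibrate to (cm/s)
#' @param purkinje_cv conduction velocity of the Purkinje network (cm/s)
#' @param n_segments wall segments per ventricle
#' @param hf_factor passive stiffening factor applied to every scenario
#' @param n_beats_cell paced beats used to reach the cell steady state
#' @return list of class `study_setup`
#' @export
study_setup <- function(seed = 1L, target_nodes = 3000, bcl = 600,
                        target_cv = 60, purkinje_cv = 300, n_segments = 18,
                        hf_factor = 5, n_beats_cell = 20) {
  mesh <- make_biventricular_mesh(
    geometry_config(target_nodes = target_nodes, seed = seed))
  tree <- make_purkinje_tree(mesh, purkinje_config(cv = purkinje_cv,
                                                   seed = seed))
  cable <- make_cable(length = 40 * mesh$h, n_nodes = 41)
  cal <- calibrate_cv(cable, target_cv = target_cv, dt = 0.05)
  cell <- run_paced_cell(cell_params("endo"),
                         pacing_protocol(bcl = bcl,
                                         n_beats = n_beats_cell))
  tr <- cell$trace
  last <- tr[tr$beat == max(tr$beat), ]
  ca <- data.frame(time = last$time - min(last$time),
                   ca = 1000 * last$ca_i)  # mM -> uM
  myo <- apply_hf_stiffening(myofilament_params(), hf_factor)
  structure(list(
    mesh = mesh, tree = tree, d_coef = cal$d_coef,
    measured_cv = cal$measured_cv, ca = ca, bcl = bcl,
    myo_params = myo, circ_params = circulation_params(),
    n_segments = n_segments, hf_factor = hf_factor,
    cell_steady = cell$steady, seed = seed), class = "study_setup")
}

#' Run one scenario end to end
#'
#' Electrical activation (Purkinje + monodomain) at the scenario's rhythm
#' and pacing, EAT-driven segmental mechanics coupled to the circulation
#' (with the LVAD when enabled) for `n_beats` beats, and all reported
#' metrics from the final (steady-state analysis) beat. Deterministic for a
#' fixed setup.
#'
#' @param scn a [scenario()]
#' @param setup a [study_setup()]
#' @param n_beats mechanical beats simulated (34 beats at BCL 600 ms is
#'   just over 20 s)
#' @param dt_mech mechanics/circulation step (ms)
#' @param dt_tissue monodomain step (ms)
#' @param ep_duration electrical simulation window (ms)
#' @param seg_coupling mean-field elastic coupling between the wall
#'   segments of a ventricle (normalized force per um): early-shortening
#'   segments prestretch late-activated ones, the reduced-order counterpart
#'   of 3-D fiber continuity
#' @param eat_map optional precomputed electrical result (from a scenario
#'   with the same rhythm and CRT setting) to reuse for +LVAD variants
#' @return list of class `scenario_result`
#' @export
run_scenario <- function(scn, setup, n_beats = 34, dt_mech = 0.05,
                         dt_tissue = 0.05, ep_duration = 250,
                         seg_coupling = 2, eat_map = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(setup, "study_setup"))
  if (is.null(eat_map)) {
    stim <- build_scenario_stimuli(scn, setup$tree, setup$mesh)
    ep <- monodomain_simulate(setup$mesh, stim, duration = ep_duration,
                              d_coef = setup$d_coef, dt = dt_tissue)
    eat_map <- ep$eat
  }
  longest_eat <- if (all(is.na(eat_map$eat))) NA_real_
                 else max(eat_map$eat, na.rm = TRUE)

  seg <- map_activation_to_segments(eat_map, setup$mesh, setup$n_segments)
  # per-ventricle tension weights; global wall fractions for ATP
  w_vent <- seg$weight
  w_total <- seg$n_nodes / sum(seg$n_nodes)

  circ <- unclass(setup$circ_params)
  ps <- unname(setup$myo_params["passive_scale"])
  circ["p0_lv"] <- circ["p0_lv"] * ps
  circ["p0_rv"] <- circ["p0_rv"] * ps
  lvad <- lvad_params(enabled = scn$lvad)
  lvad_ml_ms <- lvad_flow(lvad) * 1000 / 60000

  run <- coupled_run_cpp(unclass(setup$myo_params), seg$delay, w_vent,
                         as.integer(seg$ventricle == "rv"),
                         setup$ca$time, setup$ca$ca, circ, lvad_ml_ms,
                         setup$bcl, n_beats, dt_mech, 1, seg_coupling,
                         seg_coupling)
  if (isTRUE(run$neg_volume)) {
    stop(sprintf("scenario %s: negative compartment volume at t = %.1f ms",
                 scn$label, run$t_neg))
  }
  trace <- data.frame(time = run$time, p_lv = run$p_lv, v_lv = run$v_lv,
                      p_rv = run$p_rv, v_rv = run$v_rv, p_sa = run$p_sa,
                      p_la = run$p_la, q_ao = run$q_ao, q_mi = run$q_mi,
                      q_lvad = run$q_lvad, v_total = run$v_total)
  pv <- pv_metrics(trace, bcl = setup$bcl, lvad = lvad)

  # per-segment mechanics of the final beat
  sl0 <- unname(setup$myo_params["sl0"])
  strain_mat <- (run$seg_sl - sl0) / sl0
  mats <- vapply(seq_len(ncol(strain_mat)), function(s) {
    compute_mat(run$seg_time, strain_mat[, s])
  }, numeric(1))
  mat_df <- data.frame(segment = seg$segment, mat = mats)
  eat_df <- data.frame(segment = seg$segment, eat = seg$delay)
  emd <- compute_emd(mat_df, eat_df)
  atp <- total_atp(run$seg_time, run$seg_e_rate, w_total)

  # snapshots: end-systole = minimal LV volume of the analysis beat,
  # end-diastole = maximal
  beat_w <- trace$time >= max(trace$time) - setup$bcl
  tb <- trace[beat_w, ]
  t_es <- tb$time[which.min(tb$v_lv)] - (max(trace$time) - setup$bcl)
  t_ed <- tb$time[which.max(tb$v_lv)] - (max(trace$time) - setup$bcl)
  snap_row <- function(tt) which.min(abs(run$seg_time - tt))
  snapshots <- list(
    tension_es = run$seg_tension[snap_row(t_es), ],
    atp_rate_es = run$seg_e_rate[snap_row(t_es), ],
    strain_ed = strain_mat[snap_row(t_ed), ])

  structure(list(
    scenario = scn, longest_eat = longest_eat,
    mean_mat = emd$mean_mat, mean_emd = emd$mean_emd,
    mean_eat_seg = emd$mean_eat, emd_map = emd$map,
    n_seg_excluded = emd$n_excluded, pv = pv, atp_total = atp,
    snapshots = snapshots, segments = seg, eat = eat_map,
    trace = trace, seg_time = run$seg_time,
    seg_strain = strain_mat), class = "scenario_result")
}

#' Run the seven-scenario study
#'
#' Sinus, LBBB, LBBB+CRT, LBBB+CRT+LVAD, RBBB, RBBB+CRT and RBBB+CRT+LVAD
#' on the shared synthetic geometry. The +LVAD variants reuse the electrical
#' activation of their CRT counterparts (the device enters the mechanical
#' computation only).
#'
#' @param setup a [study_setup()]
#' @param ... passed to [run_scenario()]
#' @return list with `results` (named list of `scenario_result`) and
#'   `table` (one row of summary metrics per condition)
#' @export
run_study <- function(setup, ...) {
  scns <- list(
    sinus = scenario("sinus"),
    lbbb = scenario("lbbb"),
    lbbb_crt = scenario("lbbb", crt = TRUE),
    lbbb_crt_lvad = scenario("lbbb", crt = TRUE, lvad = TRUE),
    rbbb = scenario("rbbb"),
    rbbb_crt = scenario("rbbb", crt = TRUE),
    rbbb_crt_lvad = scenario("rbbb", crt = TRUE, lvad = TRUE))
  results <- list()
  ep_cache <- list()
  for (nm in names(scns)) {
    scn <- scns[[nm]]
    key <- paste0(scn$rhythm, "_", scn$crt)
    eat_map <- ep_cache[[key]]
    res <- run_scenario(scn, setup, eat_map = eat_map, ...)
    ep_cache[[key]] <- res$eat
    results[[nm]] <- res
  }
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(condition = nm,
               edv = r$pv$edv, esv = r$pv$esv, sv = r$pv$sv,
               ef = r$pv$ef, co = r$pv$co,
               longest_eat = r$longest_eat, mean_mat = r$mean_mat,
               mean_emd = r$mean_emd, atp = r$atp_total,
               peak_p_lv = r$pv$peak_p_lv,
               aortic_open_ms = r$pv$aortic_open_ms)
  }))
  list(results = results, table = tab)
}

#' Stroke metrics from end-diastolic and end-systolic volumes
#'
#' @param edv,esv volumes (mL), `edv >= esv`
#' @param bcl beat length (ms) for the heart-rate-based cardiac output
#' @return list with `sv` (mL), `ef` (percent) and `co` (L/min)
#' @export
stroke_metrics <- function(edv, esv, bcl = 600) {
  if (any(edv < esv)) stop("EDV must be >= ESV")
  sv <- edv - esv
  list(sv = sv, ef = 100 * sv / edv, co = sv * (60000 / bcl) / 1000)
}

#' Published hemodynamic summary table (transcribed)
#'
#' The printed per-condition hemodynamics and timing metrics of the source
#' study (EDV, ESV, CO, EF, longest EAT, average MAT, average EMD), used as
#' input for the effect-size summary; volumes in mL, CO in L/min, EF in
#' percent, times in ms. EF and volumes are not reported under LVAD support.
#'
#' @return data.frame, one row per condition
#' @export
reference_hemodynamics <- function() {
  data.frame(
    condition = c("sinus", "lbbb", "lbbb_crt", "lbbb_crt_lvad",
                  "rbbb", "rbbb_crt", "rbbb_crt_lvad"),
    edv = c(88, 90, 89, NA, 87, 88, NA),
    esv = c(55, 60, 57, NA, 54, 55, NA),
    co = c(3.4, 3, 3.2, 3.9, 3.4, 3.4, 4),
    ef = c(38, 33.4, 36, NA, 38, 38, NA),
    longest_eat = c(120, 173, 138, 138, 164, 136, 136),
    mean_mat = c(157, 188, 148, 144, 162, 157, 155),
    mean_emd = c(78, 79, 71, 67, 80, 81, 79))
}

pct_reduction <- function(ref, treated) round(100 * (ref - treated) / ref, 1)

#' Effect summary across scenarios
#'
#' Percent reductions (untreated condition as denominator, one decimal) of
#' longest EAT, average MAT, average EMD and ATP under CRT and CRT+LVAD for
#' each block, plus absolute CO deltas (L/min, one decimal).
#'
#' @param tab data.frame with columns `condition`, `longest_eat`,
#'   `mean_mat`, `mean_emd`, `co` and optionally `atp`; conditions named as
#'   in [run_study()]
#' @return data.frame with `comparison`, `metric`, `reference`, `treated`,
#'   `value`, `unit`
#' @export
summarize_effects <- function(tab) {
  need <- c("lbbb", "lbbb_crt", "lbbb_crt_lvad", "rbbb", "rbbb_crt",
            "rbbb_crt_lvad")
  missing <- setdiff(need, tab$condition)
  if (length(missing)) {
    stop("missing scenario(s): ", paste(missing, collapse = ", "))
  }
  g <- function(cond, metric) tab[[metric]][tab$condition == cond]
  rows <- list()
  add <- function(comparison, metric, ref_cond, trt_cond, value, unit) {
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, metric = metric, reference = ref_cond,
      treated = trt_cond, value = value, unit = unit)
  }
  for (blk in c("lbbb", "rbbb")) {
    for (trt in c("crt", "crt_lvad")) {
      tc <- paste0(blk, "_", trt)
      add(paste0(blk, "_", trt), "longest_eat", blk, tc,
          pct_reduction(g(blk, "longest_eat"), g(tc, "longest_eat")),
          "% reduction")
      add(paste0(blk, "_", trt), "mean_mat", blk, tc,
          pct_reduction(g(blk, "mean_mat"), g(tc, "mean_mat")),
          "% reduction")
      add(paste0(blk, "_", trt), "mean_emd", blk, tc,
          pct_reduction(g(blk, "mean_emd"), g(tc, "mean_emd")),
          "% reduction")
      if (!is.null(tab$atp)) {
        add(paste0(blk, "_", trt), "atp", blk, tc,
            pct_reduction(g(blk, "atp"), g(tc, "atp")), "% reduction")
      }
      add(paste0(blk, "_", trt), "co", blk, tc,
          round(g(tc, "co") - g(blk, "co"), 1), "L/min delta")
    }
  }
  do.call(rbind, rows)
}
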
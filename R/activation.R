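#' Purkinje-network activation times
#'
#' Propagates the His-root activation to every terminal at the network's
#' conduction velocity: an unblocked terminal activates at
#' `root_time + path_length / cv`. Terminals distal to a blocked bundle are
#' marked unactivated-by-Purkinje (`NA`).
#'
#' @param tree a [purkinje_tree()]
#' @param root_time activation time of the root (ms)
#' @param block character vector of blocked branch labels (subset of
#'   `c("left", "right")`)
#' @return data.frame with columns `node`, `tissue_node`, `branch`, `time`
#'   (ms; `NA` when blocked) and `blocked`
#' @export
purkinje_activation <- function(tree, root_time = 0, block = character(0)) {
  stopifnot(inherits(tree, "purkinje_tree"))
  n <- nrow(tree$nodes)
  dist <- rep(NA_real_, n)
  dist[tree$root] <- 0
  # children lists
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$from)
  queue <- tree$root
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (ei in kids[[as.character(v)]]) {
      w <- tree$edges$to[ei]
      dist[w] <- dist[v] + tree$edges$length[ei]
      queue <- c(queue, w)
    }
  }
  term <- tree$terminals
  if (any(is.na(dist[term$node]))) {
    bad <- term$node[is.na(dist[term$node])]
    stop("disconnected terminal node(s): ", paste(bad, collapse = ", "))
  }
  cv_cm_ms <- tree$cv / 1000
  branch <- tree$branch[term$node]
  blocked <- branch %in% block
  time <- root_time + dist[term$node] / cv_cm_ms
  time[blocked] <- NA_real_
  data.frame(node = term$node, tissue_node = term$tissue_node,
             branch = branch, time = time, blocked = blocked)
}

#' Conduction operator of a tissue mesh
#'
#' Assembles the axis-wise finite-difference diffusion operator
#' `sum_a D_a d2/dxa2` on the mesh lattice (units 1/ms). The operator is
#' symmetric with zero row sums on the no-flux boundary, so the diffusion
#' term conserves total voltage.
#'
#' @param mesh a `tissue_mesh`
#' @param d_coef diffusion coefficient(s) (cm^2/ms); scalar or one value per
#'   axis
#' @return a sparse symmetric `dgCMatrix`
#' @export
conduction_laplacian <- function(mesh, d_coef) {
  stopifnot(inherits(mesh, "tissue_mesh"), all(d_coef > 0))
  if (length(d_coef) == 1) d_coef <- rep(d_coef, 3)
  e <- mesh$edges
  w <- d_coef[e$axis] / mesh$h^2
  i <- c(e$from, e$to, e$from, e$to)
  j <- c(e$to, e$from, e$from, e$to)
  x <- c(w, w, -w, -w)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(mesh$n, mesh$n))
}

#' Conduction coefficient from tissue resistivity
#'
#' Converts per-axis cellular resistivity (kOhm cm), surface-to-volume ratio
#' (1/cm) and membrane capacitance (uF/cm^2) into the monodomain diffusion
#' coefficient `1 / (rho * S * Cm)` in cm^2/ms.
#'
#' @param rho resistivity per axis (kOhm cm)
#' @param s surface-to-volume ratio per axis (1/cm)
#' @param cm membrane capacitance (uF/cm^2)
#' @return diffusion coefficient(s) (cm^2/ms)
#' @export
conduction_coefficient <- function(rho, s, cm = 1) {
  stopifnot(all(rho > 0), all(s > 0), cm > 0)
  1 / (rho * s * cm)
}

#' Monodomain tissue simulation
#'
#' Operator-split reaction-diffusion solve on a `tissue_mesh`: the membrane
#' model is advanced per node (Rush-Larsen with voltage-capped substeps), and
#' diffusion is advanced implicitly on the fixed sparse conduction operator.
#' Electrical activation time (EAT) is recorded online per node at the first
#' upward crossing of `eat_threshold`, linearly interpolated between steps.
#'
#' @param mesh a `tissue_mesh`
#' @param stimuli data.frame with columns `node`, `time`, `duration`,
#'   `amplitude` (pA/pF, inward negative); may have zero rows
#' @param duration simulated time (ms)
#' @param d_coef diffusion coefficient(s) (cm^2/ms)
#' @param dt time step (ms)
#' @param probes node indices whose voltage traces are recorded
#' @param sample_dt probe sampling interval (ms)
#' @param eat_threshold activation threshold (mV)
#' @param dv_max reaction substep voltage cap (mV)
#' @param params optional list with `endo`, `mid`, `epi` [cell_params()]
#' @param state0 optional 17 x n matrix of initial states
#' @return list with `eat` (data.frame `node`, `eat`; `NA` = unactivated),
#'   `longest_eat`, `probe` (data.frame of probe voltages), `final_state`
#' @export
monodomain_simulate <- function(mesh, stimuli, duration, d_coef,
                                dt = 0.05, probes = integer(0),
                                sample_dt = 1, eat_threshold = -50,
                                dv_max = 0.2, params = NULL, state0 = NULL) {
  mesh_validate(mesh)
  stopifnot(duration > 0, dt > 0, all(d_coef > 0))
  if (is.null(params)) {
    params <- list(endo = cell_params("endo"), mid = cell_params("mid"),
                   epi = cell_params("epi"))
  }
  if (is.null(state0)) {
    state0 <- matrix(unclass(cell_state()), nrow = 17, ncol = mesh$n)
  }
  if (nrow(stimuli) > 0) {
    stopifnot(all(stimuli$node >= 1), all(stimuli$node <= mesh$n),
              all(stimuli$duration > 0))
  }
  lap <- conduction_laplacian(mesh, d_coef)
  stim_mat <- if (nrow(stimuli) == 0) {
    matrix(numeric(0), ncol = 4)
  } else {
    cbind(stimuli$node, stimuli$time, stimuli$duration, stimuli$amplitude)
  }
  ct <- as.integer(mesh$cell_type) - 1L  # 0 endo, 1 mid, 2 epi
  res <- monodomain_cpp(state0, ct, unclass(params$endo),
                        unclass(params$mid), unclass(params$epi),
                        lap@p, lap@i, lap@x, stim_mat, duration, dt,
                        dv_max, eat_threshold, as.integer(probes), sample_dt)
  if (isTRUE(res$unstable)) {
    stop(sprintf("monodomain instability (non-finite voltage) at t = %.3f ms",
                 res$t_fail))
  }
  probe_df <- NULL
  if (length(probes)) {
    probe_df <- data.frame(time = res$probe_time)
    for (q in seq_along(probes)) {
      probe_df[[paste0("v", probes[q])]] <- res$probe_v[, q]
    }
  }
  list(eat = data.frame(node = seq_len(mesh$n), eat = res$eat),
       longest_eat = if (all(is.na(res$eat))) NA_real_
                     else max(res$eat, na.rm = TRUE),
       probe = probe_df, final_state = res$final_state)
}

#' Measure conduction velocity on a calibration cable
#'
#' Stimulates the cable's left end and measures the planar conduction
#' velocity between two interior probes at 25 and 75 percent of cable
#' length, using the -50 mV activation-time rule.
#'
#' @param cable a 1-D `tissue_mesh` from [make_cable()]
#' @param d_coef diffusion coefficient (cm^2/ms)
#' @param dt integration step (ms)
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms)
#' @param eat_threshold activation threshold (mV)
#' @return measured velocity (cm/s), or `NA` if the wave does not reach
#'   both probes
#' @export
measure_cable_cv <- function(cable, d_coef, dt = 0.02, stim_amp = -52,
                             stim_dur = 2, eat_threshold = -50) {
  n <- cable$n
  p1 <- round(0.25 * (n - 1)) + 1L
  p2 <- round(0.75 * (n - 1)) + 1L
  len <- max(cable$coords[, 1]) - min(cable$coords[, 1])
  dur <- 1.5 * len / 0.02 + 20  # generous window at >= 20 cm/s
  # stimulate the leftmost 2% of the cable so ignition does not depend on
  # the lattice spacing relative to the diffusion length
  n_stim <- max(2L, ceiling(0.02 * n))
  stim <- data.frame(node = seq_len(n_stim), time = 0,
                     duration = stim_dur, amplitude = stim_amp)
  res <- monodomain_simulate(cable, stim, duration = dur, d_coef = d_coef,
                             dt = dt, eat_threshold = eat_threshold)
  t1 <- res$eat$eat[p1]; t2 <- res$eat$eat[p2]
  if (is.na(t1) || is.na(t2) || t2 <= t1) return(NA_real_)
  dist <- abs(cable$coords[p2, 1] - cable$coords[p1, 1])
  unname(1000 * dist / (t2 - t1))
}

#' Calibrate the conduction coefficient to a target velocity
#'
#' Finds the diffusion coefficient for which the measured planar conduction
#' velocity on a 1-D calibration cable (activation at the -50 mV crossing,
#' probes at 25 and 75 percent of cable length) matches the target within
#' tolerance. Uses the quadratic CV-diffusion scaling as the update rule with
#' a bisection fallback.
#'
#' @param cable a 1-D `tissue_mesh` from [make_cable()]
#' @param target_cv target conduction velocity (cm/s)
#' @param d_init initial coefficient guess (cm^2/ms)
#' @param tol relative tolerance on the measured velocity
#' @param max_iter iteration cap
#' @param dt integration step for the calibration runs (ms)
#' @return list with `d_coef`, `measured_cv` (cm/s) and `iterations`
#' @export
calibrate_cv <- function(cable, target_cv = 60, d_init = 0.00154,
                         tol = 0.005, max_iter = 12, dt = 0.02) {
  stopifnot(target_cv > 0, d_init > 0)
  d <- d_init
  lo <- NA_real_; hi <- NA_real_
  for (it in seq_len(max_iter)) {
    cv <- measure_cable_cv(cable, d, dt = dt)
    if (is.na(cv)) {          # propagation failed: need stronger coupling
      lo <- max(lo, d, na.rm = TRUE)
      d <- d * 4
      next
    }
    if (abs(cv - target_cv) / target_cv < tol) {
      return(list(d_coef = d, measured_cv = cv, iterations = it))
    }
    if (cv < target_cv) lo <- if (is.na(lo)) d else max(lo, d)
    else hi <- if (is.na(hi)) d else min(hi, d)
    d_new <- d * (target_cv / cv)^2
    if (!is.na(lo) && !is.na(hi) && (d_new <= lo || d_new >= hi)) {
      d_new <- sqrt(lo * hi)
    }
    d <- d_new
  }
  stop(sprintf(
    "CV calibration failed to converge; searched interval [%g, %g]",
    if (is.na(lo)) 0 else lo, if (is.na(hi)) Inf else hi))
}

#' Scenario descriptor
#'
#' One of the study conditions: rhythm (sinus or a bundle branch block),
#' optional CRT pacing, optional LVAD support. The CRT site defaults to the
#' LV free wall for LBBB and the RV endocardial apex for RBBB.
#'
#' @param rhythm `"sinus"`, `"lbbb"` or `"rbbb"`
#' @param crt logical; add a CRT pacing stimulus
#' @param lvad logical; enable the constant-flow assist device (mechanics
#'   only; the electrical setup is shared with the CRT-only variant)
#' @param crt_site `"lv_free_wall"`, `"rv_apex"` or `"rv_septal_base"`;
#'   `NULL` picks the default for the rhythm
#' @param crt_time CRT stimulus time within the beat (ms)
#' @return list of class `scenario`
#' @export
scenario <- function(rhythm = c("sinus", "lbbb", "rbbb"), crt = FALSE,
                     lvad = FALSE, crt_site = NULL, crt_time = 0) {
  rhythm <- match.arg(rhythm)
  if (crt && rhythm == "sinus") stop("CRT is defined for block rhythms only")
  if (is.null(crt_site)) {
    crt_site <- switch(rhythm, lbbb = "lv_free_wall", rbbb = "rv_apex",
                       sinus = NA_character_)
  }
  if (crt) {
    crt_site <- match.arg(crt_site,
                          c("lv_free_wall", "rv_apex", "rv_septal_base"))
  }
  label <- paste0(rhythm, if (crt) "_crt" else "",
                  if (lvad) "_lvad" else "")
  structure(list(rhythm = rhythm, crt = crt, lvad = lvad,
                 crt_site = crt_site, crt_time = crt_time, label = label),
            class = "scenario")
}

blocked_branches <- function(rhythm) {
  switch(rhythm, sinus = character(0), lbbb = "left", rbbb = "right")
}

#' CRT pacing-site nodes
#'
#' Returns a small set of mesh nodes for a named pacing site: the LV lateral
#' free wall midway between apex and base, the RV endocardial apex, or the RV
#' side of the basal septum.
#'
#' @param mesh a `tissue_mesh`
#' @param site `"lv_free_wall"`, `"rv_apex"` or `"rv_septal_base"`
#' @param k number of nodes returned
#' @return integer vector of node indices
#' @export
crt_site_nodes <- function(mesh,
                           site = c("lv_free_wall", "rv_apex",
                                    "rv_septal_base"),
                           k = 3) {
  site <- match.arg(site)
  co <- mesh$lattice
  cand <- switch(site,
    lv_free_wall = which(mesh$region == "lv_free_wall" &
                           mesh$level == "mid"),
    rv_apex = which(mesh$ventricle == "rv" & mesh$cell_type == "endo" &
                      mesh$level == "apex"),
    rv_septal_base = which(mesh$region == "septum" & mesh$level == "base" &
                             mesh$cell_type %in% c("endo", "mid")))
  if (length(cand) == 0) {
    stop("no mesh nodes carry the requested site label: ", site)
  }
  anchor <- switch(site,
    lv_free_wall = c(-mesh$config$lv_axes[1], 0,
                     mean(range(co[cand, 3]))),
    rv_apex = c(co[cand[which.min(co[cand, 3])], 1:2],
                min(co[cand, 3])),
    rv_septal_base = c(co[cand[which.max(co[cand, 3])], 1:2],
                       max(co[cand, 3])))
  d2 <- colSums((t(co[cand, , drop = FALSE]) - anchor)^2)
  cand[order(d2)[seq_len(min(k, length(cand)))]]
}

#' Build the tissue stimulus list for a scenario
#'
#' Purkinje terminal activations (with the scenario's bundle block applied)
#' become suprathreshold current injections at their bound tissue nodes and
#' terminal times; CRT adds a stimulus at the configured site and pacing
#' time. The identical electrical setup is reused for the +LVAD variants.
#'
#' @param scn a [scenario()]
#' @param tree a [purkinje_tree()]
#' @param mesh a `tissue_mesh`
#' @param stim_amp stimulus amplitude (pA/pF)
#' @param stim_dur stimulus duration (ms)
#' @param stim_radius footprint radius of each injection site (cm); defaults
#'   to 1.6 lattice spacings so a junction ignites its neighbourhood (a
#'   point source on a lattice cannot overcome the diffusive sink)
#' @return data.frame with columns `node`, `time`, `duration`, `amplitude`
#' @export
build_scenario_stimuli <- function(scn, tree, mesh, stim_amp = -52,
                                   stim_dur = 2, stim_radius = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (is.null(stim_radius)) stim_radius <- 1.6 * mesh$h
  act <- purkinje_activation(tree, root_time = 0,
                             block = blocked_branches(scn$rhythm))
  live <- act[!act$blocked, ]
  expand_site <- function(node, time) {
    d2 <- colSums((t(mesh$lattice) - mesh$lattice[node, ])^2)
    nodes <- which(d2 <= stim_radius^2 &
                     mesh$ventricle == mesh$ventricle[node])
    data.frame(node = nodes, time = time, duration = stim_dur,
               amplitude = stim_amp)
  }
  out <- do.call(rbind, c(
    lapply(seq_len(nrow(live)), function(i) {
      expand_site(live$tissue_node[i], live$time[i])
    }),
    list(data.frame(node = integer(0), time = numeric(0),
                    duration = numeric(0), amplitude = numeric(0)))))
  if (scn$crt) {
    nodes <- crt_site_nodes(mesh, scn$crt_site)
    out <- rbind(out, do.call(rbind, lapply(nodes, expand_site,
                                            time = scn$crt_time)))
  }
  if (nrow(out) == 0) {
    warning("scenario produces no stimuli (all branches blocked, no CRT)")
    return(out)
  }
  # a node stimulated by several overlapping sites keeps the earliest
  out <- out[order(out$time), ]
  out[!duplicated(out$node), ]
}
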
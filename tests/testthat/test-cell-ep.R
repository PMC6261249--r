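test_that("zero conductances give zero currents and the sum identity holds", {
  zero <- as.list(setNames(rep(0, 12),
                           c("g_na", "g_k1", "g_to", "g_kr", "g_ks", "g_cal",
                             "k_naca", "p_nak", "g_pca", "g_pk", "g_bca",
                             "g_bna")))
  cur <- ionic_currents(cell_state(), cell_params("endo", overrides = zero))
  expect_true(all(abs(cur) < 1e-14))

  # summation identity across a spread of states and all cell variants
  for (ct in c("endo", "mid", "epi")) {
    p <- cell_params(ct)
    for (v in c(-86, -60, -20, 0, 25)) {
      s <- cell_state(list(V = v, ca_i = 3e-4, ca_sr = 0.5, m = 0.3,
                           h = 0.4, d = 0.2, f = 0.8))
      cur <- ionic_currents(s, p)
      parts <- cur[setdiff(names(cur), "i_ion")]
      expect_equal(unname(cur["i_ion"]), sum(parts), tolerance = 1e-12)
    }
  }
})

test_that("non-finite state fields are rejected with a named diagnostic", {
  s <- cell_state()
  s["na_i"] <- NaN
  expect_error(ionic_currents(s, cell_params()), "na_i")
  s2 <- cell_state(list(ca_i = 1e-4))
  s2["h"] <- 1.5
  expect_error(ionic_currents(s2, cell_params()), "h")
})

test_that("calcium flux formulas match their closed forms", {
  p <- cell_params("endo")
  # leak vanishes when SR and cytosolic calcium are equal
  s <- cell_state(list(ca_i = 2e-4, ca_sr = 2e-4))
  fl <- calcium_fluxes(s, p)
  expect_equal(fl$i_leak, 0)
  # leak sign follows the gradient
  expect_gt(calcium_fluxes(cell_state(list(ca_sr = 0.5)), p)$i_leak, 0)
  expect_lt(calcium_fluxes(cell_state(list(ca_i = 4e-4, ca_sr = 1e-4)),
                           p)$i_leak, 0)
  # SERCA uptake half-saturates at ca_i = k_up
  s2 <- cell_state(list(ca_i = unname(unclass(p)["k_up"])))
  expect_equal(calcium_fluxes(s2, p)$i_up,
               unname(unclass(p)["vmax_up"]) / 2)
  # uptake is bounded by its maximum
  s3 <- cell_state(list(ca_i = 0.05))
  expect_lt(calcium_fluxes(s3, p)$i_up, unname(unclass(p)["vmax_up"]))
  expect_error(calcium_fluxes(cell_state(list(ca_i = 1e-4, ca_sr = 1e-9)),
                              p), NA)
})

test_that("SR flux balance over one beat matches the SR calcium change", {
  p <- cell_params("endo")
  res <- run_paced_cell(p, pacing_protocol(n_beats = 1), sample_dt = 0.25)
  tr <- res$trace
  pp <- unclass(p)
  net <- tr$i_up - tr$i_leak - tr$i_rel
  lhs <- sum(diff(tr$time) * (head(net, -1) + tail(net, -1)) / 2)
  sr_total <- tr$ca_sr + tr$ca_sr * pp["buf_sr"] / (tr$ca_sr + pp["k_bufsr"])
  rhs <- (tail(sr_total, 1) - sr_total[1]) / (pp["v_c"] / pp["v_sr"])
  expect_equal(lhs, unname(rhs), tolerance = 0.02)
})

test_that("a resting unpaced cell drifts by less than 1 mV over 600 ms", {
  expect_warning(
    res <- run_paced_cell(cell_params("endo"),
                          pacing_protocol(n_beats = 1, stim_amp = 0)),
    "capture")
  expect_lt(max(abs(res$trace$v - res$trace$v[1])), 1)
})

test_that("step_cell preserves equilibrium and rejects bad steps", {
  p <- cell_params("endo", overrides = as.list(setNames(
    rep(0, 12), c("g_na", "g_k1", "g_to", "g_kr", "g_ks", "g_cal",
                  "k_naca", "p_nak", "g_pca", "g_pk", "g_bca", "g_bna"))))
  s <- cell_state()
  s2 <- step_cell(s, p, i_stim = 0, dt = 1)
  expect_equal(unname(s2["V"]), unname(s["V"]))  # dV/dt = 0 with I_ion = 0
  expect_error(step_cell(s, p, dt = 0), "dt")
  expect_error(step_cell(s, p, dt = -0.1), "dt")
})

test_that("voltage trace converges as the step is refined", {
  p <- cell_params("endo")
  v_at <- function(dt) {
    run_paced_cell(p, pacing_protocol(n_beats = 1, dt = dt))$trace$v
  }
  v1 <- v_at(0.02); v2 <- v_at(0.01); v4 <- v_at(0.005)
  err12 <- max(abs(v1 - v2))
  err24 <- max(abs(v2 - v4))
  expect_lt(err12, 1)      # halving dt moves the trace by under 1 mV
  expect_lt(err24, err12)  # and the error shrinks with the step
})

test_that("a suprathreshold stimulus elicits an action potential", {
  res <- run_paced_cell(cell_params("endo"), pacing_protocol(n_beats = 1))
  expect_gt(max(res$trace$v), 10)
  expect_true(all(res$captured))
})

test_that("subthreshold pacing is reported as failure to capture", {
  expect_warning(
    res <- run_paced_cell(cell_params("endo"),
                          pacing_protocol(n_beats = 1, stim_amp = -2)),
    "capture")
  expect_false(any(res$captured))
})

test_that("a zero-beat protocol returns empty traces", {
  res <- run_paced_cell(cell_params("endo"), pacing_protocol(n_beats = 0))
  expect_equal(nrow(res$trace), 0)
  expect_true(is.na(res$analysis_beat))
})

test_that("pacing to steady state stabilizes the calcium transient", {
  res <- get_paced_endo()
  b <- res$beats
  nb <- nrow(b)
  expect_true(res$steady)
  expect_lt(abs(b$peak_ca_i[nb] - b$peak_ca_i[nb - 1]) / b$peak_ca_i[nb - 1],
            0.01)
})

test_that("midmyocardial cells have longer APD than epicardial cells", {
  apd <- function(ct) {
    r <- run_paced_cell(cell_params(ct), pacing_protocol(n_beats = 3))
    tail(r$beats$apd90, 1)
  }
  expect_gt(apd("mid"), apd("epi"))
})

test_that("gates stay in [0,1] and concentrations positive along a paced run", {
  res <- run_paced_cell(cell_params("mid"), pacing_protocol(n_beats = 2))
  fs <- res$final_state
  gates <- c("m", "h", "j", "d", "f", "fca", "r", "s", "xr1", "xr2", "xs",
             "g")
  expect_true(all(fs[gates] >= 0 & fs[gates] <= 1))
  expect_true(all(fs[c("ca_i", "ca_sr", "na_i", "k_i")] > 0))
  expect_true(all(res$trace$ca_i > 0))
})

test_that("fixed-step integration matches a stiff-solver oracle within 1 mV", {
  p <- cell_params("endo")
  rhs <- function(t, y, parms) {
    istim <- if (t < 1) -52 else 0
    list(cell_derivatives(structure(y, class = "cell_state"), p, istim))
  }
  times <- seq(0, 600, by = 1)
  orc <- deSolve::ode(y = unclass(cell_state()), times = times, func = rhs,
                      parms = NULL, method = "lsoda", rtol = 1e-8,
                      atol = 1e-10, hmax = 0.5)
  mine <- run_paced_cell(p, pacing_protocol(n_beats = 1))$trace$v
  n <- min(length(mine), nrow(orc))
  expect_lt(max(abs(mine[seq_len(n)] - orc[seq_len(n), "V"])), 1)
})
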
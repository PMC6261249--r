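test_that("afterload force is the series-elastic spring law", {
  expect_equal(afterload_force(2.2, 2.2, 5), 0)
  expect_equal(afterload_force(2.3, 2.2, 2), 0.2)
  expect_equal(afterload_force(c(1.8, 2.0, 2.5), 2.2, 0), c(0, 0, 0))
  expect_error(afterload_force(2.2, 2.2, -1), "non-negative")
})

test_that("integral_force matches closed forms and a refined-grid oracle", {
  t <- seq(0, 100, by = 1)
  z <- rep(0, length(t))
  expect_equal(integral_force(t, z, z, 0, z, t = 100), 0)
  # constant net force c integrates to c*t
  expect_equal(integral_force(t, rep(0.3, length(t)), z, 0,
                              rep(0.1, length(t)), t = 50), 0.2 * 50)
  # smooth traces against a 100x refined trapezoid oracle
  f <- function(x) 0.5 + 0.4 * sin(x / 18) + 0.1 * cos(x / 7)
  g <- function(x) 0.05 * x / 100
  tc <- seq(0, 100, by = 0.1)
  tf <- seq(0, 100, by = 0.001)
  oracle <- sum(diff(tf) * (head(f(tf) - g(tf), -1) +
                              tail(f(tf) - g(tf), -1)) / 2)
  zc <- rep(0, length(tc))
  mine <- integral_force(tc, f(tc), zc, 0, g(tc), t = 100)
  expect_equal(mine, oracle, tolerance = 1e-3)
  expect_error(integral_force(c(0, 2, 1), 1:3, 1:3, 0, 1:3), "increasing")
})

test_that("sl_step follows the printed sarcomere-length ODE", {
  p <- myofilament_params()
  zero_bal <- list(f_active = 0, f_passive = 0, f_preload = 0,
                   f_afterload = 0)
  # isometric: SL fixed whatever the forces
  st <- list(sl = 2.2, intf = 0)
  big <- list(f_active = 5, f_passive = 1, f_preload = 0, f_afterload = 0)
  expect_equal(sl_step(st, big, p, 0.1, "isometric")$sl, 2.2)
  # isotonic equilibrium: zero integral force at SL0
  st2 <- sl_step(list(sl = unname(p["sl0"]), intf = 0), zero_bal, p, 0.1,
                 "isotonic")
  expect_equal(st2$sl, unname(p["sl0"]))
  # frozen constant integral force: trajectory matches the linear-ODE
  # closed form SL(t) = SL0 + (C/visc)(1 - exp(-visc t / mass))
  C <- -0.5
  dt <- 0.01
  st3 <- list(sl = unname(p["sl0"]), intf = C)
  for (i in seq_len(5000)) st3 <- sl_step(st3, zero_bal, p, dt, "isotonic")
  t_end <- 5000 * dt
  sl_exact <- unname(p["sl0"]) + (C / p["visc"]) *
    (1 - exp(-p["visc"] * t_end / p["mass"]))
  expect_equal(st3$sl, unname(sl_exact), tolerance = 1e-3)
  expect_error(sl_step(st3, zero_bal, p, 0), "dt")
})

test_that("ATP rate is the detachment-overlap product", {
  expect_equal(atp_rate(list(g_xbt = 0, sovf_thick = 0.7)), 0)
  expect_equal(atp_rate(list(g_xbt = 5, sovf_thick = 0.4)), 2)
  expect_equal(atp_rate(5, 0.4), 2)
  expect_error(atp_rate(-1, 0.5), "g_xbt")
  expect_error(atp_rate(5, 1.4), "sovf_thick")
})

test_that("twitch tension is driven by the calcium transient", {
  p <- myofilament_params()
  ca <- default_ca()
  tw <- run_twitch(ca, p, mode = "isometric")
  # a flat diastolic transient produces almost no tension
  flat <- data.frame(time = c(0, 600), ca = c(0.09, 0.09))
  twd <- run_twitch(flat, p, mode = "isometric")
  expect_lt(twd$summary$peak_tension, 0.05 * tw$summary$peak_tension)
  # tension relaxes back by the end of the cycle at steady pacing
  last <- tw$trace[tw$trace$cycle == max(tw$trace$cycle), ]
  expect_lt(abs(tail(last$tension, 1) - last$tension[1]),
            0.02 * max(last$tension))
  # rises and falls within the cycle
  imax <- which.max(last$tension)
  expect_gt(imax, 1)
  expect_lt(imax, nrow(last))
  expect_error(run_twitch(data.frame(time = c(0, 600), ca = c(-1, 1)), p),
               "positive")
})

test_that("peak tension grows monotonically with calcium amplitude", {
  p <- myofilament_params()
  peaks <- vapply(c(0.6, 0.8, 1.0, 1.3, 1.6), function(s) {
    ca <- make_ca_transient(peak = 0.09 + (1.45 - 0.09) * s)
    run_twitch(ca, p, mode = "isometric")$summary$peak_tension
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("passive stiffening scales the passive curve pointwise", {
  p1 <- myofilament_params()
  p5 <- apply_hf_stiffening(myofilament_params(), 5)
  sls <- seq(1.7, 2.35, by = 0.05)
  expect_equal(passive_force(sls, p5), 5 * passive_force(sls, p1),
               tolerance = 1e-12)
  # doubling passive stiffness leaves isometric active tension unchanged
  ca <- default_ca()
  t1 <- run_twitch(ca, p1, mode = "isometric")$summary$peak_tension
  t2 <- run_twitch(ca, apply_hf_stiffening(myofilament_params(), 2),
                   mode = "isometric")$summary$peak_tension
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("twitch state quantities respect their ranges", {
  tw <- run_twitch(default_ca(), myofilament_params(), mode = "isotonic")
  expect_true(all(tw$trace$e_rate >= 0))
  expect_true(all(tw$trace$sovf_thick >= 0 & tw$trace$sovf_thick <= 1))
  expect_true(all(tw$trace$gxb_t >= 0))
  expect_true(all(is.finite(tw$trace$sl)))
  # E equals the product identity on the trace
  expect_equal(tw$trace$e_rate, tw$trace$gxb_t * tw$trace$sovf_thick,
               tolerance = 1e-12)
})

test_that("cycle ATP matches a refined-grid quadrature oracle", {
  ca <- default_ca()
  p <- myofilament_params()
  coarse <- run_twitch(ca, p, mode = "isometric", sample_dt = 2)
  fine <- run_twitch(ca, p, mode = "isometric", sample_dt = 0.05)
  expect_equal(coarse$summary$cycle_atp, fine$summary$cycle_atp,
               tolerance = 1e-3)
})
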
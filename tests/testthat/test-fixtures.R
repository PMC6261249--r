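test_that("mesh generation is deterministic and validly labelled", {
  cfg <- geometry_config(target_nodes = 800, seed = 7)
  m1 <- make_biventricular_mesh(cfg)
  m2 <- make_biventricular_mesh(cfg)
  expect_identical(m1, m2)
  expect_true(mesh_validate(m1))
  expect_true(all(levels(m1$ventricle) %in% c("lv", "rv")))
  expect_gt(sum(m1$ventricle == "lv"), 0)
  expect_gt(sum(m1$ventricle == "rv"), 0)
  # a different seed only moves the cosmetic jitter, not the lattice
  m3 <- make_biventricular_mesh(geometry_config(target_nodes = 800,
                                                seed = 8))
  expect_identical(m1$lattice, m3$lattice)
  expect_false(identical(m1$coords, m3$coords))
})

test_that("equal layer fractions give near-equal node counts per layer", {
  m <- make_biventricular_mesh(geometry_config())
  frac <- as.numeric(table(m$cell_type)) / m$n
  expect_true(all(abs(frac - 1 / 3) < 0.05 / 3))
})

test_that("no lattice edge joins endocardium directly to epicardium", {
  m <- make_biventricular_mesh(geometry_config(target_nodes = 1500))
  lev <- c(endo = 3L, mid = 2L, epi = 1L)
  jump <- abs(lev[m$cell_type[m$edges$from]] -
                lev[m$cell_type[m$edges$to]])
  expect_true(all(jump <= 1))
})

test_that("infeasible wall settings are rejected", {
  expect_error(geometry_config(lv_inner_scale = 1.2))
  expect_error(geometry_config(layer_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("purkinje trees are deterministic with endocardial terminals", {
  mesh <- make_biventricular_mesh(geometry_config(target_nodes = 1500))
  t1 <- make_purkinje_tree(mesh, purkinje_config(seed = 3))
  t2 <- make_purkinje_tree(mesh, purkinje_config(seed = 3))
  expect_identical(t1, t2)
  expect_true(all(mesh$cell_type[t1$terminals$tissue_node] == "endo"))
  # left-branch terminals live in the LV, right in the RV
  br <- t1$branch[t1$terminals$node]
  vent <- mesh$ventricle[t1$terminals$tissue_node]
  expect_true(all(vent[br == "left"] == "lv"))
  expect_true(all(vent[br == "right"] == "rv"))
  # all root-to-terminal path lengths finite and positive
  act <- purkinje_activation(t1)
  expect_true(all(is.finite(act$time) & act$time > 0))
})

test_that("calibration cables have the requested spacing and probes", {
  cab <- make_cable(2, 201)
  expect_equal(cab$n, 201)
  expect_equal(cab$h, 0.01)
  expect_equal(diff(cab$coords[, 1])[1], 0.01)
  p1 <- round(0.25 * 200) + 1
  p2 <- round(0.75 * 200) + 1
  expect_true(p1 > 1 && p2 < 201)  # interior by construction
  expect_error(make_cable(2, 2))
})

test_that("the idealized calcium transient meets its contract", {
  ca <- make_ca_transient(peak = 1.3, diastolic = 0.1, time_to_peak = 25,
                          tau_decay = 90, bcl = 600)
  expect_equal(max(ca$ca), 1.3)
  expect_equal(ca$ca[1], 0.1)
  expect_equal(ca$time[which.max(ca$ca)], 25)
  # flat when peak equals diastolic
  flat <- make_ca_transient(peak = 0.1, diastolic = 0.1)
  expect_true(all(flat$ca == 0.1))
  # area under one cycle against a refined-grid quadrature oracle
  fine <- make_ca_transient(peak = 1.3, diastolic = 0.1, time_to_peak = 25,
                            tau_decay = 90, bcl = 600, dt = 0.01)
  trapz <- function(d) sum(diff(d$time) * (head(d$ca, -1) +
                                             tail(d$ca, -1)) / 2)
  expect_equal(trapz(ca), trapz(fine), tolerance = 1e-3)
  expect_error(make_ca_transient(peak = 0.05, diastolic = 0.1))
})

test_that("generated meshes pass the activation module's checks unchanged", {
  mesh <- make_biventricular_mesh(geometry_config(target_nodes = 800))
  expect_silent(mesh_validate(mesh))
  L <- conduction_laplacian(mesh, 0.002)
  expect_equal(dim(L), c(mesh$n, mesh$n))
})
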
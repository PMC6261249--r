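# a hand-built two-branch tree: root -> (left arm of 2 edges), root -> right
tiny_tree <- function(cv = 60) {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0), c(-1, 0, 0))
  edges <- data.frame(from = c(1, 2, 1), to = c(2, 3, 4),
                      length = c(2, 1, 1))
  purkinje_tree(nodes, edges, root = 1,
                terminals = data.frame(node = c(3, 4),
                                       tissue_node = c(10, 20)),
                branch = c("his", "left", "left", "right"), cv = cv)
}

test_that("purkinje activation is path length over conduction velocity", {
  act <- purkinje_activation(tiny_tree(), root_time = 0)
  # 3 cm at 60 cm/s = 50 ms
  expect_equal(act$time[act$tissue_node == 10], 50)
  expect_equal(act$time[act$tissue_node == 20], 1 / 0.06)
  # root_time shifts every terminal rigidly
  act2 <- purkinje_activation(tiny_tree(), root_time = 7)
  expect_equal(act2$time, act$time + 7)
})

test_that("bundle block suppresses exactly the blocked branch", {
  act <- purkinje_activation(tiny_tree(), block = "left")
  expect_true(is.na(act$time[act$branch == "left"]))
  expect_false(any(is.na(act$time[act$branch == "right"])))
  expect_equal(act$time[act$branch == "right"],
               purkinje_activation(tiny_tree())$time[act$branch == "right"])
  both <- purkinje_activation(tiny_tree(), block = c("left", "right"))
  expect_true(all(is.na(both$time)))
})

test_that("tree invariants are enforced by the constructor", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  # a node with two parents is not a tree
  bad <- data.frame(from = c(1, 1), to = c(2, 2), length = c(1, 1))
  expect_error(purkinje_tree(nodes, bad, 1,
                             data.frame(node = 3, tissue_node = 1),
                             c("his", "left", "left")), "tree")
  # non-positive edge lengths rejected
  bad2 <- data.frame(from = c(1, 2), to = c(2, 3), length = c(1, 0))
  expect_error(purkinje_tree(nodes, bad2, 1,
                             data.frame(node = 3, tissue_node = 1),
                             c("his", "left", "left")))
})

test_that("the conduction operator is symmetric with zero row sums", {
  mesh <- make_cable(2, 21)
  L <- conduction_laplacian(mesh, 0.001)
  expect_lt(max(abs(L - Matrix::t(L))), 1e-15)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-15)
  # anisotropic coefficients scale the matching axis
  m2 <- make_biventricular_mesh(geometry_config(target_nodes = 400,
                                                jitter_frac = 0))
  L2 <- conduction_laplacian(m2, c(0.001, 0.002, 0.003))
  expect_lt(max(abs(L2 - Matrix::t(L2))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(L2))), 1e-12)
})

test_that("no stimuli means no activation anywhere", {
  cab <- make_cable(1, 21)
  res <- monodomain_simulate(cab, data.frame(node = integer(0),
                                             time = numeric(0),
                                             duration = numeric(0),
                                             amplitude = numeric(0)),
                             duration = 30, d_coef = 0.001)
  expect_true(all(is.na(res$eat$eat)))
  expect_true(is.na(res$longest_eat))
})

test_that("a planar wave activates the cable linearly in distance", {
  cab <- make_cable(2, 101)
  cal <- cached("cal_coarse", calibrate_cv(cab, 60, dt = 0.02))
  stim <- data.frame(node = 1:2, time = 0, duration = 2, amplitude = -52)
  res <- monodomain_simulate(cab, stim, duration = 80, d_coef = cal$d_coef,
                             dt = 0.02)
  i <- 26:76  # interior quarter-to-three-quarter window
  x <- cab$coords[i, 1]
  eat <- res$eat$eat[i]
  expect_false(any(is.na(eat)))
  # monotone non-decreasing with distance from the stimulus
  expect_true(all(diff(eat) >= 0))
  fit <- coef(lm(eat ~ x))
  cv_fit <- 1000 / fit[2]  # cm/s
  expect_lt(abs(cv_fit - 60) / 60, 0.05)
})

test_that("waves from both ends collide at the midpoint", {
  cab <- make_cable(2, 101)
  cal <- cached("cal_coarse", calibrate_cv(cab, 60, dt = 0.02))
  one <- monodomain_simulate(cab, data.frame(node = 1:2, time = 0,
                                             duration = 2, amplitude = -52),
                             duration = 80, d_coef = cal$d_coef, dt = 0.02)
  n <- cab$n
  two <- monodomain_simulate(cab,
                             data.frame(node = c(1, 2, n - 1, n), time = 0,
                                        duration = 2, amplitude = -52),
                             duration = 80, d_coef = cal$d_coef, dt = 0.02)
  expect_equal(which.max(two$eat$eat), (n + 1) / 2, tolerance = 2)
  expect_equal(two$longest_eat / one$longest_eat, 0.5, tolerance = 0.1)
})

test_that("CV calibration hits the target and scales as sqrt(D)", {
  cab <- make_cable(2, 101)
  cal <- cached("cal_coarse", calibrate_cv(cab, 60, dt = 0.02))
  expect_lt(abs(cal$measured_cv - 60), 1.2)
  # idempotence: recalibrating from the answer returns the same coefficient
  cal2 <- calibrate_cv(cab, 60, d_init = cal$d_coef, dt = 0.02)
  expect_equal(cal2$d_coef, cal$d_coef, tolerance = 0.05)
  # diffusion scaling law: doubling D multiplies CV by about sqrt(2)
  cv2 <- measure_cable_cv(cab, 2 * cal$d_coef, dt = 0.02)
  expect_equal(cv2 / cal$measured_cv, sqrt(2), tolerance = 0.05)
})

test_that("scenario stimuli follow rhythm, block and pacing site", {
  setup <- get_setup()
  mesh <- setup$mesh; tree <- setup$tree
  sinus <- build_scenario_stimuli(scenario("sinus"), tree, mesh)
  expect_setequal(as.character(unique(mesh$ventricle[sinus$node])),
                  c("lv", "rv"))
  lbbb <- build_scenario_stimuli(scenario("lbbb"), tree, mesh)
  expect_true(all(mesh$ventricle[lbbb$node] == "rv"))
  lbbb_crt <- build_scenario_stimuli(scenario("lbbb", crt = TRUE), tree,
                                     mesh)
  lv_nodes <- lbbb_crt$node[mesh$ventricle[lbbb_crt$node] == "lv"]
  expect_gt(length(lv_nodes), 0)
  expect_true(all(mesh$region[lv_nodes] == "lv_free_wall"))
  expect_true(all(lbbb_crt$time[match(lv_nodes, lbbb_crt$node)] == 0))
  # RBBB default site is the RV endocardial apex
  rbbb_crt <- build_scenario_stimuli(scenario("rbbb", crt = TRUE), tree,
                                     mesh)
  extra <- setdiff(rbbb_crt$node,
                   build_scenario_stimuli(scenario("rbbb"), tree,
                                          mesh)$node)
  expect_true(all(mesh$ventricle[extra] == "rv"))
  expect_true(all(mesh$level[extra] == "apex"))
})

test_that("a fully blocked tree without CRT yields no stimuli", {
  setup <- get_setup()
  # single-branch tree bound to the LV: an LBBB scenario blocks everything
  lv_endo <- which(setup$mesh$cell_type == "endo" &
                     setup$mesh$ventricle == "lv")[1]
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  tree <- purkinje_tree(nodes,
                        data.frame(from = 1, to = 2, length = 1), 1,
                        data.frame(node = 2, tissue_node = lv_endo),
                        branch = c("his", "left"))
  expect_warning(
    stim <- build_scenario_stimuli(scenario("lbbb"), tree, setup$mesh),
    "no stimuli")
  expect_equal(nrow(stim), 0)
})

test_that("CRT site options resolve to labelled mesh regions", {
  mesh <- get_setup()$mesh
  fw <- crt_site_nodes(mesh, "lv_free_wall")
  expect_true(all(mesh$region[fw] == "lv_free_wall"))
  ap <- crt_site_nodes(mesh, "rv_apex")
  expect_true(all(mesh$ventricle[ap] == "rv" & mesh$level[ap] == "apex"))
  sb <- crt_site_nodes(mesh, "rv_septal_base")
  expect_true(all(mesh$region[sb] == "septum" & mesh$level[sb] == "base"))
})
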
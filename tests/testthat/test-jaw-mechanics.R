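# FE patch tests on a structured box, then the jaw-cycle machinery on the
# default rudiment.

box_patch <- function(h = 0.25) {
  m <- make_box_mesh(L = c(1, 1, 1), h = h)
  nd <- m$nodes
  bot <- which(abs(nd[, 3]) < 1e-9)
  corner <- which(rowSums(abs(nd)) < 1e-9)
  edge <- which(abs(nd[, 1] - 1) < 1e-9 & abs(nd[, 2]) < 1e-9 &
                  abs(nd[, 3]) < 1e-9)
  bcs <- bc_set(list(list(nodes = bot, axes = 3L),
                     list(nodes = corner, axes = 1:3),
                     list(nodes = edge, axes = 2L)), nrow(nd))
  faces <- boundary_faces(m)
  fc <- (nd[faces[, 1], 3] + nd[faces[, 2], 3] + nd[faces[, 3], 3]) / 3
  list(mesh = m, bcs = bcs, top = faces[fc > 1 - 1e-9, ])
}

test_that("material model reproduces the published stiffness values", {
  mat <- material_model()
  expect_equal(mat$E[mat$region == "MC"], 142.01)
  expect_equal(unique(mat$nu), 0.3)
  expect_equal(mat$E[mat$region == "interzone"], 142.01 * 0.00025)
  expect_equal(attr(mat, "interzone_fraction"), 2.5e-4)
  expect_error(material_model(nu = 0.5), "Poisson")
  expect_error(material_model(E_cartilage = -1), "positive")
})

test_that("uniaxial compression patch test: sigma_h = -p/3 everywhere", {
  p <- 10
  bp <- box_patch()
  F <- traction_loads(bp$mesh, bp$top, c(0, 0, -p))
  sol <- solve_elasticity(bp$mesh, material_model(), bp$bcs, F)
  expect_lt(max(abs(sol$sigma_h + p / 3)) / (p / 3), 1e-6)
  expect_lt(max(abs(sol$stress_nodes[, 3] + p)) / p, 1e-6)
  # closed-form top displacement u_z = -p L / E
  top_nodes <- which(abs(bp$mesh$nodes[, 3] - 1) < 1e-9)
  expect_equal(unname(sol$u[top_nodes, 3]),
               rep(-p / 142.01, length(top_nodes)), tolerance = 1e-6)
  # zero loads give zero response
  sol0 <- solve_elasticity(bp$mesh, material_model(), bp$bcs,
                           numeric(3 * nrow(bp$mesh$nodes)))
  expect_equal(max(abs(sol0$u)), 0)
  expect_equal(max(abs(sol0$sigma_h)), 0)
})

test_that("stresses are linear in the load factor", {
  bp <- box_patch(h = 0.5)
  F <- traction_loads(bp$mesh, bp$top, c(0, 0, -3))
  s1 <- solve_elasticity(bp$mesh, material_model(), bp$bcs, F)
  s2 <- solve_elasticity(bp$mesh, material_model(), bp$bcs, F,
                         load_factor = 2.5)
  expect_equal(s2$sigma_h, 2.5 * s1$sigma_h, tolerance = 1e-9)
  expect_equal(s2$u, 2.5 * s1$u, tolerance = 1e-9)
})

test_that("sign convention: compression gives negative sigma_h in the column", {
  bp <- box_patch(h = 0.25)
  F <- traction_loads(bp$mesh, bp$top, c(0, 0, -5))
  sol <- solve_elasticity(bp$mesh, material_model(), bp$bcs, F)
  expect_true(all(sol$sigma_h < 0))
})

test_that("cantilever tip deflection approaches the beam closed form", {
  # slender beam 2 x 2 x 20, tip load; Timoshenko closed form with shear
  # correction (Euler-Bernoulli plus shear term) as the reference
  L <- 20; c_ <- 2; E <- 142.01; nu <- 0.3
  m <- make_box_mesh(L = c(L, c_, c_), h = 0.5)
  nd <- m$nodes
  root <- which(abs(nd[, 1]) < 1e-9)
  bcs <- bc_set(list(list(nodes = root, axes = 1:3)), nrow(nd))
  tipn <- which(abs(nd[, 1] - L) < 1e-9)
  P <- 0.05
  loads <- tibble::tibble(node = tipn, fx = 0, fy = 0,
                          fz = -P / length(tipn))
  sol <- solve_elasticity(m, material_model(E), bcs, loads)
  I <- c_^4 / 12; G <- E / (2 * (1 + nu)); A <- c_^2; k <- 5 / 6
  w_ref <- P * L^3 / (3 * E * I) + P * L / (k * G * A)
  w_fe <- mean(abs(sol$u[tipn, 3]))
  # linear tets are stiff in bending; accept the coarse-mesh range and check
  # refinement moves toward the closed form
  expect_gt(w_fe / w_ref, 0.6)
  expect_lt(w_fe / w_ref, 1.05)
  m2 <- make_box_mesh(L = c(L, c_, c_), h = 0.25)
  root2 <- which(abs(m2$nodes[, 1]) < 1e-9)
  tip2 <- which(abs(m2$nodes[, 1] - L) < 1e-9)
  sol2 <- solve_elasticity(m2, material_model(E),
                           bc_set(list(list(nodes = root2, axes = 1:3)),
                                  nrow(m2$nodes)),
                           tibble::tibble(node = tip2, fx = 0, fy = 0,
                                          fz = -P / length(tip2)))
  w_fe2 <- mean(abs(sol2$u[tip2, 3]))
  expect_gt(w_fe2, w_fe)            # converging upward toward the reference
  expect_lt(abs(w_fe2 / w_ref - 1), 0.25)
})

test_that("hydrostatic stress conventions", {
  expect_equal(hydrostatic(diag(c(-3, 0, 0))), -1)
  shear <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(hydrostatic(shear), 0)
  expect_equal(hydrostatic(5 * diag(3)), 5)
  expect_equal(hydrostatic(cbind(1, 2, 3, 0, 0, 0)), 2)
})

test_that("average hydrostatic stress over a cycle", {
  h <- structure(list(increments = lapply(1:6, function(k) rep(2, 5))),
                 class = "stress_history")
  expect_equal(average_hydrostatic(h), rep(2, 5))
  h2 <- structure(list(increments = lapply(1:6, function(k) k * rep(1, 3))),
                  class = "stress_history")
  expect_equal(average_hydrostatic(h2), rep(3.5, 3))
  h3 <- structure(list(increments = c(lapply(1:3, function(k) rep(0.7, 4)),
                                      lapply(1:3, function(k) rep(-0.7, 4)))),
                  class = "stress_history")
  expect_equal(average_hydrostatic(h3), rep(0, 4))
})

test_that("compressive clamp", {
  x <- c(-2, 0, 3, -0.5)
  expect_equal(compressive_clamp(x), c(-2, 0, 0, -0.5))
  expect_equal(compressive_clamp(c(1, 2)), c(0, 0))
  expect_equal(compressive_clamp(c(-1, -2)), c(-1, -2))
})

test_that("nodal gradients are exact for linear fields, zero for constants", {
  m <- make_box_mesh(L = c(4, 4, 4), h = 1)
  f <- 0.25 * m$nodes[, 3]
  g <- nodal_gradient(f, m)
  expect_equal(g[, 1], rep(0, nrow(g)), tolerance = 1e-8)
  expect_equal(g[, 2], rep(0, nrow(g)), tolerance = 1e-8)
  expect_equal(g[, 3], rep(0.25, nrow(g)), tolerance = 1e-8)  # boundary too
  gc <- nodal_gradient(rep(3.2, nrow(m$nodes)), m)
  expect_lt(max(abs(gc)), 1e-10)
  expect_error(nodal_gradient(c(f[-1], NA), m), "finite")
})

test_that("jaw cycle stores 2n increments with linear ramps and the
           physiological stress pattern at the joint", {
  m <- default_mesh()
  mat <- material_model()
  bcs <- default_jaw_bcs(m)
  loads <- muscle_load_set(m, age = 4)
  expect_equal(sort(loads$magnitude),
               sort(c(2.84, 1.25, 1.50, 1.50)))
  cal <- calibrate_muscle_forces(m, mat, bcs, loads, 37.2)
  hist <- simulate_jaw_cycle(m, mat, bcs, loads, n_increments = 5,
                             scale = cal$scale)
  expect_length(hist$increments, 10)
  expect_equal(hist$peak_closure, 5)
  expect_equal(hist$peak_opening, 10)
  # linearity of the ramp
  expect_equal(hist$increments[[2]], 2 / 5 * hist$increments[[5]],
               tolerance = 1e-10)
  expect_equal(hist$increments[[7]], 2 / 5 * hist$increments[[10]],
               tolerance = 1e-10)
  # at peak opening the dorsal MC near the joint is tensile, ventral
  # compressive; reversed at peak closure
  mc <- jawgrowth:::region_nodes(m, "MC")
  near <- mc[m$nodes[mc, 1] < 8]
  dors <- near[m$nodes[near, 3] > 5]
  vent <- near[m$nodes[near, 3] < -5]
  sho <- hist$increments[[hist$peak_opening]]
  shc <- hist$increments[[hist$peak_closure]]
  expect_gt(mean(sho[dors]), 0)
  expect_lt(mean(sho[vent]), 0)
  expect_lt(mean(shc[dors]), 0)
  expect_gt(mean(shc[vent]), 0)
  # cycle average shows the compression peak at the level of the joint
  S <- average_hydrostatic(hist)
  expect_lt(mean(S[near]), 0)
})

test_that("muscle-force calibration reaches the target opening exactly and
           scales linearly", {
  m <- default_mesh()
  mat <- material_model()
  bcs <- default_jaw_bcs(m)
  loads <- muscle_load_set(m, age = 4)
  cal <- calibrate_muscle_forces(m, mat, bcs, loads, target_opening = 37.2)
  expect_equal(cal$achieved_opening, 37.2, tolerance = 0.1 / 37.2)
  cal2 <- calibrate_muscle_forces(m, mat, bcs, loads, target_opening = 74.4)
  expect_equal(cal2$scale, 2 * cal$scale, tolerance = 1e-8)
  # round trip: applying the scale reproduces the measured opening
  hist <- simulate_jaw_cycle(m, mat, bcs, loads, 5, scale = cal$scale)
  expect_equal(hist$opening_displacement, cal$achieved_opening,
               tolerance = 1e-8)
})

test_that("sigma_h is invariant under rotation of the global frame", {
  bp <- box_patch(h = 0.5)
  F <- traction_loads(bp$mesh, bp$top, c(0, 0, -4))
  sol <- solve_elasticity(bp$mesh, material_model(), bp$bcs, F)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mR <- bp$mesh; mR$nodes <- bp$mesh$nodes %*% t(R)
  FR <- numeric(length(F))
  Fm <- matrix(F, ncol = 3, byrow = TRUE) %*% t(R)
  FR <- as.vector(t(Fm))
  solR <- solve_elasticity(mR, material_model(), bp$bcs, FR)
  expect_equal(solR$sigma_h, sol$sigma_h, tolerance = 1e-10)
})
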
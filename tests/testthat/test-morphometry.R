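make_cyl_stack <- function(radius, n_slices = 10, n_points = 36,
                           z0 = 0, z1 = 30) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  df <- do.call(rbind, lapply(seq_len(n_slices), function(s) {
    tibble::tibble(slice = s,
                   axial_pos = z0 + (s - 1) * (z1 - z0) / (n_slices - 1),
                   point = seq_len(n_points),
                   u = radius * cos(th), v = radius * sin(th))
  }))
  shape_stack(df)
}

test_that("landmark alignment recovers rigid motions", {
  m <- make_box_mesh(L = c(30, 20, 10), h = 2.5)
  joint <- c(0, 10, 5)
  retro <- joint + 10 * c(5, 0, -10) / sqrt(125)  # along the reference dir
  jdir <- c(0, 1, 0)
  # identity case: translation only
  al <- align_to_landmarks(m$nodes, joint, retro, joint_line_dir = jdir)
  expect_equal(al$rotation, diag(3), tolerance = 1e-12)
  # rotation about ML by 30 degrees recovered exactly
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  nodesR <- m$nodes %*% t(R)
  al2 <- align_to_landmarks(nodesR, drop(R %*% joint), drop(R %*% retro),
                            joint_line_dir = drop(R %*% jdir))
  expect_equal(al2$rotation %*% R, al$rotation, tolerance = 1e-8)
  expect_equal(al2$shape, al$shape, tolerance = 1e-8)
  # general 3D rotation also recovered when the joint-line direction is given
  R3 <- al$rotation
  th2 <- 0.4; th3 <- -0.8
  Rx <- matrix(c(1, 0, 0, 0, cos(th2), sin(th2), 0, -sin(th2), cos(th2)), 3, 3)
  Rz <- matrix(c(cos(th3), sin(th3), 0, -sin(th3), cos(th3), 0, 0, 0, 1), 3, 3)
  Rg <- Rx %*% Rz
  al3 <- align_to_landmarks(m$nodes %*% t(Rg), drop(Rg %*% joint),
                            drop(Rg %*% retro),
                            joint_line_dir = drop(Rg %*% jdir))
  expect_equal(al3$shape, al$shape, tolerance = 1e-8)
  expect_error(align_to_landmarks(m$nodes, joint, joint), "coincide")
})

test_that("noisy copies align to within the noise scale", {
  set.seed(42)
  m <- default_mesh()
  pts <- m$nodes[jawgrowth:::region_nodes(m, "MC"), ]
  noise <- function() matrix(stats::rnorm(length(pts), sd = 0.2), ncol = 3)
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a <- pts + noise()
  b <- (pts + noise()) %*% t(R)
  al_b <- align_to_landmarks(b, drop(R %*% c(0, 0, 0)), drop(R %*% c(3, 0, -9)),
                             joint_line_dir = drop(R %*% c(0, 1, 0)))
  rms <- sqrt(mean(rowSums((al_b$shape -
    align_to_landmarks(a, c(0, 0, 0), c(3, 0, -9),
                       joint_line_dir = c(0, 1, 0))$shape)^2)))
  expect_lt(rms, 0.5)
})

test_that("average shape: identity, concentric cylinders, idempotence", {
  c10 <- make_cyl_stack(10)
  c20 <- make_cyl_stack(20)
  avg <- average_shape(list(c10, c20), n_slices = 10, n_points = 36)
  r <- sqrt(avg$u^2 + avg$v^2)
  expect_equal(unname(range(r)), c(15, 15), tolerance = 1e-6)
  same <- average_shape(list(c10, c10, c10), n_slices = 10, n_points = 36)
  expect_equal(unname(range(sqrt(same$u^2 + same$v^2))), c(10, 10),
               tolerance = 1e-6)
  # permutation invariance
  avg2 <- average_shape(list(c20, c10), n_slices = 10, n_points = 36)
  expect_equal(avg$u, avg2$u, tolerance = 1e-10)
  # disjoint axial ranges rejected
  far <- make_cyl_stack(10, z0 = 100, z1 = 130)
  expect_error(average_shape(list(c10, far)), "overlap")
})

test_that("anteroposterior cropping", {
  m <- make_box_mesh(L = c(40, 10, 10), h = 2.5)
  expect_error(crop_anteroposterior(m, -3), "positive")
  full <- crop_anteroposterior(m, 40)
  expect_equal(nrow(full$elems), nrow(m$elems))
  cropped <- crop_anteroposterior(m, 25)
  mm <- measure_morphometrics(cropped, region = "MC", joint_centre = c(0, 0, 0))
  expect_equal(mm$length, 25, tolerance = 2.5 / 25)
})

test_that("morphometrics of an axis-aligned box and rigid invariance", {
  m <- make_box_mesh(L = c(30, 10, 20), h = 2.5)
  mm <- measure_morphometrics(m, joint_centre = c(0, 5, 10))
  expect_equal(mm$length, 30)
  expect_equal(mm$depth, 20)
  expect_equal(mm$width, 10)
  # rotate, then align, then measure: unchanged to 1e-8
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  joint <- c(0, 5, 10); retro <- c(15, 5, 0)
  al <- align_to_landmarks(m$nodes %*% t(R), drop(R %*% joint),
                           drop(R %*% retro),
                           joint_line_dir = drop(R %*% c(0, 1, 0)))
  base <- align_to_landmarks(m$nodes, joint, retro,
                             joint_line_dir = c(0, 1, 0))
  mm2 <- measure_morphometrics(al$shape, joint_centre = c(0, 0, 0))
  mm1 <- measure_morphometrics(base$shape, joint_centre = c(0, 0, 0))
  expect_equal(unlist(mm2), unlist(mm1), tolerance = 1e-8)
  expect_error(measure_morphometrics(m$nodes[0, , drop = FALSE]), "empty")
})

test_that("monotonicity: enlarging one axis increases exactly that measure", {
  m <- default_mesh()
  base <- measure_morphometrics(m)
  for (axis in 1:3) {
    m2 <- m
    m2$nodes[, axis] <- m2$nodes[, axis] * 1.15
    m2$landmarks$joint_centre <- m$landmarks$joint_centre *
      ifelse(seq_len(3) == axis, 1.15, 1)
    mm <- measure_morphometrics(m2)
    lab <- c("length", "width", "depth")[axis]
    expect_gt(mm[[lab]], base[[lab]] * 1.14)
    others <- setdiff(c("length", "depth", "width"), lab)
    for (o in others) {
      expect_equal(mm[[o]], base[[o]], tolerance = 0.03)
    }
  }
})

test_that("percent change arithmetic and error cases", {
  b <- tibble::tibble(length = 30, depth = 20, width = 10)
  a <- tibble::tibble(length = 41.1, depth = 28.6, width = 11.1)
  pc <- percent_change(b, a)
  expect_equal(pc$length, 37, tolerance = 1e-10)
  expect_equal(pc$depth, 43, tolerance = 1e-10)
  expect_equal(pc$width, 11, tolerance = 1e-10)
  expect_equal(unlist(percent_change(b, b)), c(length = 0, depth = 0, width = 0))
  half <- b; half$depth <- 10
  expect_equal(percent_change(b, half)$depth, -50)
  zero <- b; zero$length <- 0
  expect_error(percent_change(zero, a), "positive")
})

test_that("mesh-derived shape stacks trace the region outline", {
  m <- default_mesh()
  st <- mesh_to_shape_stack(m, "MC", n_slices = 15, n_points = 48)
  expect_s3_class(st, "shape_stack")
  # a mid-rod slice radius should match the analytic rod radius to ~h
  mid <- st[st$slice == 10, ]
  x0 <- mid$axial_pos[1]
  r_true <- m$spec$mc_radius_profile(x0 - m$spec$derived$g2)
  r_mesh <- sqrt(mid$u^2 + mid$v^2)
  expect_lt(abs(stats::median(r_mesh) - r_true), m$h)
})
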
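test_that("Delaunay links: complete graph on a tetrahedron, cutoff respected", {
  P <- regular_tetrahedron()
  expect_equal(nrow(build_links(P, cutoff = Inf)), 6)
  expect_equal(nrow(build_links(P, cutoff = 0.5)), 0)
  expect_error(build_links(P[1:3, ], cutoff = Inf), "4 centroids")
  flat <- cbind(matrix(runif(20), 10), 0)
  expect_error(build_links(flat, cutoff = Inf), "coplanar")
})

test_that("Delaunay edge enumeration matches an independent tessellation", {
  # scipy.spatial.Delaunay (qhull) as the independent oracle
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 11)
  pos <- jawgrowth:::centroid_positions(cells)
  links <- build_links(cells, cutoff = Inf)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(pos), csv, row.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np, sys\n",
    "from scipy.spatial import Delaunay\n",
    "p = np.loadtxt('", csv, "', delimiter=',', skiprows=1)\n",
    "t = Delaunay(p).simplices\n",
    "e = set()\n",
    "for s in t:\n",
    "    for i in range(4):\n",
    "        for j in range(i+1,4):\n",
    "            e.add((min(s[i],s[j]), max(s[i],s[j])))\n",
    "print(len(e))"))), stdout = TRUE)
  expect_equal(nrow(links), as.integer(out[length(out)]))
})

test_that("conserved link pairs: identity, linear scaling, conserved count", {
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 25, 4, seed = 12)
  p1 <- jawgrowth:::centroid_positions(cells)
  same <- tracked_pair(cells, as_set(p1, cells$cell_id, 4.5), 43200)
  lp <- conserved_link_pairs(same, cutoff = Inf)
  expect_equal(as.matrix(lp[, c("l2x", "l2y", "l2z")]),
               as.matrix(lp[, c("l1x", "l1y", "l1z")]),
               ignore_attr = TRUE)
  scaled <- tracked_pair(cells, as_set(1.1 * p1, cells$cell_id, 4.5), 43200)
  lp2 <- conserved_link_pairs(scaled, cutoff = Inf)
  expect_equal(as.matrix(lp2[, c("l2x", "l2y", "l2z")]),
               1.1 * as.matrix(lp2[, c("l1x", "l1y", "l1z")]),
               ignore_attr = TRUE)
  expect_equal(nrow(lp), nrow(build_links(cells, cutoff = Inf)))
})

test_that("velocity gradient: translation, dilation, uniaxial, rotation", {
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 25, 4, seed = 13)
  p1 <- jawgrowth:::centroid_positions(cells)
  dt <- 43200
  mk <- function(p2) conserved_link_pairs(
    tracked_pair(cells, as_set(p2, cells$cell_id, 4.5), dt), cutoff = Inf)
  # pure translation -> zero tensor
  t0 <- velocity_gradient_roi(mk(sweep(p1, 2, c(-3, 2, 5))), dt)
  expect_lt(max(abs(t0$tensor)), 1e-18)
  # isotropic scaling k = 0.3 -> (k/dt) I = 6.944e-6/s
  ti <- velocity_gradient_roi(mk(1.3 * p1), dt)
  expect_equal(diag(ti$tensor), rep(0.3 / dt, 3), tolerance = 1e-10)
  expect_equal(unname(diag(ti$tensor)[1]), 6.944e-6, tolerance = 1e-4)
  expect_lt(max(abs(ti$tensor - diag(diag(ti$tensor)))), 1e-12)
  # uniaxial stretch along VD
  p2 <- p1; p2[, 3] <- 1.2 * p2[, 3]
  tu <- velocity_gradient_roi(mk(p2), dt)
  expect_equal(tu$tensor, diag(c(0, 0, 0.2 / dt)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # small rigid rotation: symmetric part vanishes to first order
  th <- 0.05
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  tr <- velocity_gradient_roi(mk(p1 %*% t(R)), dt)
  expect_lt(norm(tr$tensor, "F"), th^2 / dt)
})

test_that("invalid ROIs are flagged, not zeroed", {
  lp <- tibble::tibble(l1x = 1, l1y = 0, l1z = 0, l2x = 1, l2y = 0, l2z = 0)
  t1 <- velocity_gradient_roi(lp, delta_t = 100)
  expect_false(t1$valid)
  expect_match(t1$reason, "few links")
  # 5 collinear links: singular texture matrix
  lp2 <- tibble::tibble(l1x = c(1, 2, 3, 4, 5), l1y = 0, l1z = 0,
                        l2x = c(1, 2, 3, 4, 5), l2y = 0, l2z = 0)
  t2 <- velocity_gradient_roi(lp2, delta_t = 100)
  expect_false(t2$valid)
})

test_that("axis labelling is a bijection with deterministic tie-breaking", {
  dt <- 43200
  T <- diag(c(5e-6, 3e-6, 1e-6))  # eigenvectors = anatomical axes
  gt <- jawgrowth:::finalize_growth_tensor(T, 10)
  expect_equal(unname(labelled_rate(gt, "AP")), 5e-6)
  expect_equal(unname(labelled_rate(gt, "ML")), 3e-6)
  expect_equal(unname(labelled_rate(gt, "VD")), 1e-6)
  expect_equal(unname(gt$angles_deg), rep(0, 3), tolerance = 1e-7)
  # rotate eigenframe 10 degrees about AP: VD/ML labels follow, angles 10
  th <- 10 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  T2 <- R %*% diag(c(5e-6, 3e-6, 1e-6)) %*% t(R)
  gt2 <- jawgrowth:::finalize_growth_tensor(T2, 10)
  expect_equal(unname(labelled_rate(gt2, "AP")), 5e-6, tolerance = 1e-9)
  expect_equal(unname(gt2$angles_deg[["VD"]]), 10, tolerance = 1e-6)
  expect_equal(unname(gt2$angles_deg[["ML"]]), 10, tolerance = 1e-6)
  # 45-degree tie between VD and ML: deterministic across repeats
  th <- pi / 4
  R45 <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  T3 <- R45 %*% diag(c(5e-6, 3e-6, 1e-6)) %*% t(R45)
  l1 <- jawgrowth:::finalize_growth_tensor(T3, 10)
  l2 <- jawgrowth:::finalize_growth_tensor(T3, 10)
  expect_identical(l1$axis_labels, l2$axis_labels)
})

test_that("growth map recovers a global affine deformation in every ROI", {
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 14)
  p1 <- jawgrowth:::centroid_positions(cells)
  A <- diag(c(1.25, 1.05, 1.4)); A[1, 3] <- 0.06; A[2, 1] <- -0.03
  pair <- tracked_pair(cells, as_set(p1 %*% t(A), cells$cell_id, 4.5), 43200)
  map <- assemble_growth_map(pair, roi_grid(pair), cutoff = Inf)
  expected <- (A + t(A)) / 2 - diag(3)
  expected <- expected / 43200
  for (r in which(map$rois$valid)) {
    expect_equal(map$tensors[[r]]$tensor, expected, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # single-ROI consistency: one cube holding everything equals the full set
  grid1 <- roi_grid(pair, cube_side = 200, origin = c(-100, -100, -100))
  map1 <- assemble_growth_map(pair, grid1, cutoff = Inf)
  full <- velocity_gradient_roi(conserved_link_pairs(pair, cutoff = Inf),
                                43200)
  expect_equal(map1$tensors[[1]]$tensor, full$tensor, tolerance = 1e-12)
})

test_that("frame objectivity: rotating inputs conjugates every tensor", {
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 15)
  p1 <- jawgrowth:::centroid_positions(cells)
  A <- diag(c(1.3, 1.1, 1.2)); A[1, 3] <- 0.05
  p2 <- p1 %*% t(A)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pair <- tracked_pair(cells, as_set(p2, cells$cell_id, 4.5), 43200)
  pairR <- tracked_pair(as_set(p1 %*% t(R), cells$cell_id, 4),
                        as_set(p2 %*% t(R), cells$cell_id, 4.5), 43200)
  t1 <- velocity_gradient_roi(conserved_link_pairs(pair, cutoff = Inf), 43200)
  t2 <- velocity_gradient_roi(conserved_link_pairs(pairR, cutoff = Inf), 43200)
  expect_equal(t2$tensor, R %*% t1$tensor %*% t(R), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("interpolation: exact at centres, linear between, nearest outside", {
  m <- default_mesh()
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 16)
  p1 <- jawgrowth:::centroid_positions(cells)
  # spatially varying synthetic map: fill two adjacent ROIs with T and 3T
  pair <- tracked_pair(cells, as_set(p1 * 1.2, cells$cell_id, 4.5), 43200)
  map <- assemble_growth_map(pair, roi_grid(pair), cutoff = Inf)
  v <- which(map$rois$valid)
  T <- diag(c(1, 2, 3)) * 1e-6
  map$tensors <- lapply(seq_along(map$tensors), function(r) {
    jawgrowth:::finalize_growth_tensor(T * if (map$rois$roi_i[r] %% 2 == 0) 1 else 3,
                                       10)
  })
  map$rois$valid <- TRUE
  r_even <- which(map$rois$roi_i %% 2 == 0)[1]
  ctr <- as.numeric(map$rois[r_even, c("cx", "cy", "cz")])
  got <- interpolate_growth(map, rbind(ctr))
  expect_equal(got[1, ], jawgrowth:::voigt6(T), tolerance = 1e-12,
               ignore_attr = TRUE)
  # midway between an adjacent even/odd pair along AP: mean of T and 3T = 2T
  nb <- which(map$rois$roi_i == map$rois$roi_i[r_even] + 1 &
                map$rois$roi_j == map$rois$roi_j[r_even] &
                map$rois$roi_k == map$rois$roi_k[r_even])
  if (length(nb) == 1) {
    mid <- (ctr + as.numeric(map$rois[nb, c("cx", "cy", "cz")])) / 2
    expect_equal(interpolate_growth(map, rbind(mid))[1, ],
                 jawgrowth:::voigt6(2 * T), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # far outside: nearest ROI tensor, still symmetric
  far <- rbind(c(1e4, 1e4, 1e4))
  vf <- interpolate_growth(map, far)
  d <- as.matrix(stats::dist(rbind(far, as.matrix(map$rois[, c("cx", "cy", "cz")]))))[1, -1]
  expect_equal(vf[1, ],
               jawgrowth:::voigt6(map$tensors[[which.min(d)]]$tensor),
               ignore_attr = TRUE)
})

test_that("default synthetic free pair: VD-labelled rates exceed ML in most ROIs", {
  m <- default_mesh()
  fld <- ground_truth_deformation("free", m)
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 17)
  pair <- advect_tracked_pair(cells, fld, 43200, noise_sd = 0, seed = 1)
  map <- assemble_growth_map(pair, roi_grid(pair,
                                            origin = m$landmarks$joint_centre))
  v <- map$rois[map$rois$valid, ]
  expect_gte(mean(v$rate_VD > v$rate_ML), 0.8)
})

test_that("eigenvalue scale matches 30-40% growth per 24 h", {
  m <- default_mesh()
  for (mode in c("free", "immobilised")) {
    fld <- ground_truth_deformation(mode, m)
    cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 18)
    pair <- advect_tracked_pair(cells, fld, 43200, noise_sd = 0.3, seed = 2)
    map <- assemble_growth_map(pair, roi_grid(pair,
                                              origin = m$landmarks$joint_centre))
    v <- map$rois[map$rois$valid, ]
    ev <- c(v$rate_VD, v$rate_AP, v$rate_ML)
    expect_true(all(ev > -5e-6 & ev < 5e-5))
  }
})

test_that("noise robustness: median eigenvalue error under 15% of the leading
           ground-truth rate", {
  m <- default_mesh()
  fld <- ground_truth_deformation("free", m)
  lead <- max(abs(fld$amplitudes))
  errs <- c()
  for (seed in 1:3) {
    cells <- sample_cell_centroids(m, "MC", 30, 4, seed = seed)
    noisy <- advect_tracked_pair(cells, fld, 43200, noise_sd = 0.3,
                                 seed = seed + 10)
    clean <- advect_tracked_pair(cells, fld, 43200, noise_sd = 0,
                                 seed = seed + 10)
    grid <- roi_grid(noisy, origin = m$landmarks$joint_centre)
    mn <- assemble_growth_map(noisy, grid)
    mc <- assemble_growth_map(clean, grid)
    for (r in seq_len(nrow(mn$rois))) {
      if (mn$rois$valid[r] && mc$rois$valid[r]) {
        errs <- c(errs, abs(mn$tensors[[r]]$eigenvalues -
                              mc$tensors[[r]]$eigenvalues))
      }
    }
  }
  expect_lt(stats::median(errs), 0.15 * lead)
})

test_that("growth map CSV round trip", {
  m <- default_mesh()
  fld <- ground_truth_deformation("free", m)
  cells <- sample_cell_centroids(m, "MC", 30, 4, seed = 19)
  pair <- advect_tracked_pair(cells, fld, 43200, noise_sd = 0, seed = 1)
  map <- assemble_growth_map(pair, roi_grid(pair,
                                            origin = m$landmarks$joint_centre))
  path <- tempfile(fileext = ".csv")
  write_growth_map_csv(map, path)
  map2 <- read_growth_map_csv(path)
  q <- rbind(c(10, 0, 0), c(25, 5, -5))
  expect_equal(interpolate_growth(map2, q), interpolate_growth(map, q),
               tolerance = 1e-9)
})
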
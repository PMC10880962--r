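#' Per-element anisotropic growth strains over a window
#'
#' Interpolates the growth map at element centroids and converts rates to
#' strains (`strain = rate * window`) along the tensor's eigenvector frame.
#'
#' @param map A `growth_map` or `node_growth_field`.
#' @param mesh A `labelled_tet_mesh`.
#' @param window Window in seconds (default 43200, one 12 h interval).
#' @param min_coverage Minimum fraction of element centroids inside the ROI
#'   lattice hull (only meaningful for ROI maps); below it an error is
#'   raised.
#' @return List with `strains` (E x 3), `frames` (list of 3x3 eigenvector
#'   matrices... stored as E x 9 matrix, columns = vec of the frame), and
#'   `voigt` (E x 6 strain tensors).
#' @export
growth_strains <- function(map, mesh, window = 43200, min_coverage = 0.02) {
  stopifnot(window > 0)
  ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
          mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  v6 <- tensor_field_at(map, mesh, ctr)
  if (inherits(map, "growth_map")) {
    valid <- map$rois[map$rois$valid, ]
    lo <- c(min(valid$cx), min(valid$cy), min(valid$cz)) - map$grid$cube_side / 2
    hi <- c(max(valid$cx), max(valid$cy), max(valid$cz)) + map$grid$cube_side / 2
    inside <- ctr[, 1] >= lo[1] & ctr[, 1] <= hi[1] &
      ctr[, 2] >= lo[2] & ctr[, 2] <= hi[2] &
      ctr[, 3] >= lo[3] & ctr[, 3] <= hi[3]
    if (mean(inside) < min_coverage) {
      stop("growth map covers only ", round(100 * mean(inside), 1),
           "% of element centroids (min ", 100 * min_coverage, "%)")
    }
  }
  ne <- nrow(v6)
  strains <- matrix(0, ne, 3)
  frames <- matrix(0, ne, 9)
  for (e in seq_len(ne)) {
    ev <- eigen(from_voigt6(v6[e, ]), symmetric = TRUE)
    strains[e, ] <- ev$values * window
    frames[e, ] <- as.vector(ev$vectors)
  }
  list(strains = strains, frames = frames, voigt = v6 * window)
}

#' @noRd
tensor_field_at <- function(map, mesh, pts) {
  if (inherits(map, "growth_map")) {
    interpolate_growth(map, pts)
  } else if (inherits(map, "node_growth_field")) {
    # element-wise mean of nodal tensors for element centroids; nearest node
    # otherwise
    if (nrow(pts) == nrow(mesh$elems)) {
      (map$tensors[mesh$elems[, 1], ] + map$tensors[mesh$elems[, 2], ] +
         map$tensors[mesh$elems[, 3], ] + map$tensors[mesh$elems[, 4], ]) / 4
    } else {
      map$tensors[nearest_row(pts, mesh$nodes), , drop = FALSE]
    }
  } else {
    stop("map must be a growth_map or node_growth_field")
  }
}

#' Apply a growth map to a mesh over a window
#'
#' Two application modes:
#' \describe{
#' \item{eigenstrain}{The growth strains enter an elastic equilibrium solve
#' as stress-free strains (the expansion-subroutine mechanics): per sub-step
#' the incremental eigenstrain load is assembled on the current geometry,
#' the displacement solved under minimal statically determinate rigid-body
#' constraints (so compatible growth is exactly stress-free up to a rigid
#' motion, which is removed by re-anchoring at the joint line), and the
#' nodes updated. Incompatible growth leaves residual stress, as it
#' should.}
#' \item{kinematic}{Nodes are advected directly through the growth-velocity
#' field `v(x) = L(x) (x - origin)` with `L` the rate-equivalent logarithm of
#' the local stretch, sub-stepped over the window; a fast, solver-free
#' oracle.}
#' }
#' Strain increments compound multiplicatively across sub-steps, so a
#' spatially uniform rate `g` applied over a window reproduces the stretch
#' `1 + g * window` that the growth estimator would report for that window.
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param map A `growth_map` or `node_growth_field`.
#' @param window Seconds (default 43200).
#' @param mode `"eigenstrain"` (default) or `"kinematic"`.
#' @param n_substeps Sub-steps per window (default 10).
#' @param materials,bcs Needed for eigenstrain mode.
#' @param origin Flow origin for kinematic mode (joint-line landmark).
#' @return The grown mesh (landmarks advected along).
#' @export
apply_growth <- function(mesh, map, window = 43200,
                         mode = c("eigenstrain", "kinematic"),
                         n_substeps = 10, materials = NULL, bcs = NULL,
                         origin = NULL) {
  mode <- match.arg(mode)
  stopifnot(window > 0, n_substeps >= 1)
  if (mode == "kinematic") {
    return(apply_growth_kinematic(mesh, map, window, n_substeps, origin))
  }
  if (is.null(materials)) stop("eigenstrain mode needs materials")
  gs <- growth_strains(map, mesh, window)
  if (!all(is.finite(gs$strains))) stop("growth strains are not finite")
  out <- mesh
  lm <- rbind(out$landmarks$joint_centre, out$landmarks$retroarticular)
  # saturation guards: a window cannot shrink material past -90% nor grow
  # past +200% (only reached by deliberately extreme sensitivity-sweep
  # values or stimulus spikes; the calibrated depth response operates far
  # below both)
  total <- pmin(pmax(gs$strains, -0.9), 2)

  # one eigenstrain increment of exponent `expo` of the window stretch on
  # the current geometry; returns updated nodes + landmark displacement, or
  # NULL if the step inverts elements
  eigen_increment <- function(nodes, lms, expo) {
    inc <- (1 + total)^expo - 1
    eg <- element_gradients(nodes, out$elems)
    tmp <- out; tmp$nodes <- nodes
    lam <- lame_parameters(materials, tmp)
    # eigenstress sigma* = lambda tr(eps*) I + 2 mu eps*, with eps* the
    # incremental stress-free strain in the element's growth frame
    R1 <- gs$frames[, 1:3]; R2 <- gs$frames[, 4:6]; R3 <- gs$frames[, 7:9]
    e1 <- inc[, 1]; e2 <- inc[, 2]; e3 <- inc[, 3]
    # eps* = sum_k e_k r_k r_k^T (vectorised over elements)
    exx <- e1 * R1[, 1]^2 + e2 * R2[, 1]^2 + e3 * R3[, 1]^2
    eyy <- e1 * R1[, 2]^2 + e2 * R2[, 2]^2 + e3 * R3[, 2]^2
    ezz <- e1 * R1[, 3]^2 + e2 * R2[, 3]^2 + e3 * R3[, 3]^2
    exy <- e1 * R1[, 1] * R1[, 2] + e2 * R2[, 1] * R2[, 2] + e3 * R3[, 1] * R3[, 2]
    eyz <- e1 * R1[, 2] * R1[, 3] + e2 * R2[, 2] * R2[, 3] + e3 * R3[, 2] * R3[, 3]
    exz <- e1 * R1[, 1] * R1[, 3] + e2 * R2[, 1] * R2[, 3] + e3 * R3[, 1] * R3[, 3]
    tr <- exx + eyy + ezz
    sxx <- lam$lambda * tr + 2 * lam$mu * exx
    syy <- lam$lambda * tr + 2 * lam$mu * eyy
    szz <- lam$lambda * tr + 2 * lam$mu * ezz
    sxy <- 2 * lam$mu * exy; syz <- 2 * lam$mu * eyz; sxz <- 2 * lam$mu * exz
    n <- nrow(nodes)
    f <- numeric(3 * n)
    for (aa in 1:4) {
      g <- eg$g[[aa]]
      fx <- eg$V * (sxx * g[, 1] + sxy * g[, 2] + sxz * g[, 3])
      fy <- eg$V * (sxy * g[, 1] + syy * g[, 2] + syz * g[, 3])
      fz <- eg$V * (sxz * g[, 1] + syz * g[, 2] + szz * g[, 3])
      idx <- out$elems[, aa]
      sq <- seq_len(n)
      f[(sq - 1L) * 3L + 1L] <- f[(sq - 1L) * 3L + 1L] + tapply_add(fx, idx, n)
      f[(sq - 1L) * 3L + 2L] <- f[(sq - 1L) * 3L + 2L] + tapply_add(fy, idx, n)
      f[(sq - 1L) * 3L + 3L] <- f[(sq - 1L) * 3L + 3L] + tapply_add(fz, idx, n)
    }
    bset <- if (is.null(bcs)) growth_pin_bcs(tmp) else bcs
    u <- solve_elasticity(tmp, materials, bset, f)$u
    # remove the rigid motion of the joint neighbourhood: grown specimens
    # stay aligned at the joint line, as measured specimens are
    u <- subtract_joint_rigid(u, nodes, lms[1, ])
    new_nodes <- nodes + u
    if (any(tet_volumes(new_nodes, out$elems) <= 0)) return(NULL)
    list(nodes = new_nodes, lms = lms + idw_field(u, nodes, lms))
  }

  for (step in seq_len(n_substeps)) {
    # tolerance-driven refinement: halve the increment (up to 8x) if element
    # quality degrades to inversion within this sub-step
    done <- FALSE
    for (halvings in 0:3) {
      m_sub <- 2^halvings
      nodes_try <- out$nodes; lm_try <- lm
      ok <- TRUE
      for (s2 in seq_len(m_sub)) {
        res <- eigen_increment(nodes_try, lm_try,
                               1 / (n_substeps * m_sub))
        if (is.null(res)) { ok <- FALSE; break }
        nodes_try <- res$nodes; lm_try <- res$lms
      }
      if (ok) {
        out$nodes <- nodes_try; lm <- lm_try; done <- TRUE
        break
      }
    }
    if (!done) {
      vol <- tet_volumes(out$nodes, out$elems)
      stop("growth inverted elements even under sub-step refinement: ",
           paste(utils::head(order(vol), 5), collapse = ", "))
    }
  }
  out$landmarks$joint_centre <- lm[1, ]
  out$landmarks$retroarticular <- lm[2, ]
  out
}

# weighted least-squares rigid (small-rotation) fit of a displacement field
# around the joint, subtracted so growth leaves the joint region un-moved
#' @noRd
subtract_joint_rigid <- function(u, nodes, joint, sigma = 10) {
  x <- sweep(nodes, 2, joint)
  w <- exp(-rowSums(x^2) / (2 * sigma^2))
  n <- nrow(x)
  zero <- numeric(n); one <- rep(1, n)
  # model u_i = t_i + (omega x x)_i, fitted by weighted normal equations
  design <- list(
    cbind(one, zero, zero, zero, x[, 3], -x[, 2]),
    cbind(zero, one, zero, -x[, 3], zero, x[, 1]),
    cbind(zero, zero, one, x[, 2], -x[, 1], zero))
  A <- matrix(0, 6, 6); b <- numeric(6)
  for (i in 1:3) {
    A <- A + crossprod(design[[i]] * w, design[[i]])
    b <- b + crossprod(design[[i]] * w, u[, i])
  }
  p <- solve(A, b)
  t_ <- p[1:3]; om <- p[4:6]
  rig <- cbind(t_[1] + om[2] * x[, 3] - om[3] * x[, 2],
               t_[2] + om[3] * x[, 1] - om[1] * x[, 3],
               t_[3] + om[1] * x[, 2] - om[2] * x[, 1])
  u - rig
}

# inverse-distance interpolation of a nodal vector field at a few points
#' @noRd
idw_field <- function(u, nodes, pts, k = 8) {
  out <- matrix(0, nrow(pts), ncol(u))
  for (p in seq_len(nrow(pts))) {
    d2 <- colSums((t(nodes) - pts[p, ])^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / pmax(d2[nn], 1e-12)
    out[p, ] <- colSums(u[nn, , drop = FALSE] * w) / sum(w)
  }
  out
}

# Growth velocity from a strain-rate tensor field: the tensor is the
# (symmetric) velocity gradient, so with the joint line anchored the
# velocity is its line integral along the ray from the origin,
#   v(x) = [ int_0^1 L(o + t (x - o)) dt ] (x - o),
# evaluated by fixed-order Gauss-Legendre quadrature. L is the
# rate-equivalent logarithm of the window stretch 1 + G * window, so that a
# uniform estimated rate g reproduces the stretch 1 + g * window exactly.
#' @noRd
growth_velocity <- function(map, mesh, pts, origin, window, n_quad = 6) {
  gl_x <- c(0.03376524, 0.16939531, 0.38069041,
            0.61930959, 0.83060469, 0.96623476)
  gl_w <- c(0.08566225, 0.18038079, 0.23395697,
            0.23395697, 0.18038079, 0.08566225)
  dx <- sweep(pts, 2, origin)
  Lbar <- matrix(0, nrow(pts), 6)
  for (q in seq_len(n_quad)) {
    sample_pts <- sweep(gl_x[q] * dx, 2, -origin)
    v6 <- tensor_field_at(map, mesh, sample_pts)
    Lbar <- Lbar + gl_w[q] * log_tensor_rate(v6, window)
  }
  cbind(Lbar[, 1] * dx[, 1] + Lbar[, 4] * dx[, 2] + Lbar[, 6] * dx[, 3],
        Lbar[, 4] * dx[, 1] + Lbar[, 2] * dx[, 2] + Lbar[, 5] * dx[, 3],
        Lbar[, 6] * dx[, 1] + Lbar[, 5] * dx[, 2] + Lbar[, 3] * dx[, 3])
}

# symmetric 3x3 product in Voigt rows (valid when the factors commute,
# as matrix powers do)
#' @noRd
sym6_mult <- function(a, b) {
  cbind(a[, 1] * b[, 1] + a[, 4] * b[, 4] + a[, 6] * b[, 6],
        a[, 4] * b[, 4] + a[, 2] * b[, 2] + a[, 5] * b[, 5],
        a[, 6] * b[, 6] + a[, 5] * b[, 5] + a[, 3] * b[, 3],
        a[, 1] * b[, 4] + a[, 4] * b[, 2] + a[, 6] * b[, 5],
        a[, 4] * b[, 6] + a[, 2] * b[, 5] + a[, 5] * b[, 3],
        a[, 1] * b[, 6] + a[, 4] * b[, 5] + a[, 6] * b[, 3])
}

# log(I + w X) / w by an 8-term Mercator series, vectorised over Voigt rows;
# accurate to ~1e-5 relative for the |eigenvalue| * window <= 0.5 regime of
# larval growth windows
#' @noRd
log_tensor_rate <- function(v6, window) {
  X <- v6 * window
  out <- X
  P <- X
  for (k in 2:8) {
    P <- sym6_mult(P, X)
    out <- out + ((-1)^(k - 1) / k) * P
  }
  out / window
}

#' @noRd
apply_growth_kinematic <- function(mesh, map, window, n_substeps, origin) {
  if (is.null(origin)) origin <- mesh$landmarks$joint_centre
  out <- mesh
  pts <- rbind(out$nodes, out$landmarks$joint_centre, out$landmarks$retroarticular)
  dt <- window / n_substeps
  for (step in seq_len(n_substeps)) {
    v1 <- growth_velocity(map, mesh, pts, origin, window)
    v2 <- growth_velocity(map, mesh, pts + 0.5 * dt * v1, origin, window)
    pts <- pts + dt * v2
  }
  n <- nrow(out$nodes)
  out$nodes <- pts[seq_len(n), , drop = FALSE]
  out$landmarks$joint_centre <- pts[n + 1, ]
  out$landmarks$retroarticular <- pts[n + 2, ]
  vol <- tet_volumes(out$nodes, out$elems)
  if (any(vol <= 0)) {
    stop("growth inverted elements: ",
         paste(utils::head(which(vol <= 0), 10), collapse = ", "))
  }
  out
}

#' Silhouette outline of a mesh region in an anatomical plane
#'
#' Projects the region's boundary triangles to the lateral (AP-VD) or ventral
#' (AP-ML) plane, rasterises the covered area and traces the 0.5 level set of
#' the occupancy, giving a closed outline at roughly mesh resolution.
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param plane `"lateral"` or `"ventral"`.
#' @param region Region label.
#' @param resolution Raster cell size (um); default half the mesh spacing.
#' @return Tibble with columns `u`, `v` (closed polyline, um) and attributes
#'   `plane`, `axes`.
#' @export
extract_outline <- function(mesh, plane = c("lateral", "ventral"),
                            region = "MC", resolution = NULL) {
  plane <- match.arg(plane)
  if (is.null(resolution)) resolution <- mesh$h / 2
  cols <- if (plane == "lateral") c(1, 3) else c(1, 2)
  faces <- boundary_faces(mesh, region)
  if (!nrow(faces)) stop("region has no surface in this plane: ", region)
  P <- mesh$nodes[, cols]
  tri <- cbind(P[faces[, 1], , drop = FALSE], P[faces[, 2], , drop = FALSE],
               P[faces[, 3], , drop = FALSE])
  lo <- c(min(tri[, c(1, 3, 5)]), min(tri[, c(2, 4, 6)])) - 2 * resolution
  hi <- c(max(tri[, c(1, 3, 5)]), max(tri[, c(2, 4, 6)])) + 2 * resolution
  gx <- seq(lo[1], hi[1], by = resolution)
  gy <- seq(lo[2], hi[2], by = resolution)
  occ <- matrix(0, length(gx), length(gy))
  for (f in seq_len(nrow(faces))) {
    ax <- tri[f, 1]; ay <- tri[f, 2]; bx <- tri[f, 3]; by <- tri[f, 4]
    cx <- tri[f, 5]; cy <- tri[f, 6]
    # skip edge-on faces: their degenerate projection would mark cells on
    # either side of the line
    if (abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) <
          1e-6 * resolution^2) next
    i0 <- max(1, findInterval(min(ax, bx, cx), gx))
    i1 <- min(length(gx), findInterval(max(ax, bx, cx), gx) + 1)
    j0 <- max(1, findInterval(min(ay, by, cy), gy))
    j1 <- min(length(gy), findInterval(max(ay, by, cy), gy) + 1)
    if (i1 < i0 || j1 < j0) next
    px <- rep(gx[i0:i1], times = j1 - j0 + 1)
    py <- rep(gy[j0:j1], each = i1 - i0 + 1)
    d1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    d2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
    d3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
    inside <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    if (any(inside)) {
      sub <- matrix(inside, i1 - i0 + 1, j1 - j0 + 1)
      occ[i0:i1, j0:j1] <- pmax(occ[i0:i1, j0:j1], sub + 0)
    }
  }
  cl <- grDevices::contourLines(gx, gy, occ, levels = 0.99)
  if (!length(cl)) stop("no outline found; plane does not intersect region")
  len <- vapply(cl, function(c1) length(c1$x), 1L)
  best <- cl[[which.max(len)]]
  out <- tibble::tibble(u = c(best$x, best$x[1]), v = c(best$y, best$y[1]))
  attr(out, "plane") <- plane
  attr(out, "axes") <- if (plane == "lateral") c("AP", "VD") else c("AP", "ML")
  out
}

#' Symmetric surface distance and morphometric differences of two meshes
#'
#' Mean and maximum symmetric surface distance from mutual closest-point
#' queries between the region surface nodes, plus per-measure percent
#' differences. The distance is the quantitative stand-in for the visual
#' outline comparisons of grown shapes.
#'
#' @param meshA,meshB Aligned `labelled_tet_mesh`es.
#' @param region Region to compare.
#' @return A `shape_comparison` tibble: `mean_dist`, `max_dist` (um),
#'   `d_length`, `d_depth`, `d_width` (percent, B relative to A).
#' @export
compare_shapes <- function(meshA, meshB, region = "MC") {
  sa <- meshA$nodes[surface_nodes(meshA, region), , drop = FALSE]
  sb <- meshB$nodes[surface_nodes(meshB, region), , drop = FALSE]
  dab <- sqrt(rowSums((sa - sb[nearest_row(sa, sb), , drop = FALSE])^2))
  dba <- sqrt(rowSums((sb - sa[nearest_row(sb, sa), , drop = FALSE])^2))
  pc <- percent_change(measure_morphometrics(meshA, region),
                       measure_morphometrics(meshB, region))
  out <- tibble::tibble(mean_dist = mean(c(dab, dba)),
                        max_dist = max(dab, dba),
                        d_length = pc$length, d_depth = pc$depth,
                        d_width = pc$width)
  class(out) <- c("shape_comparison", class(out))
  out
}
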
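#' Build a labelled tetrahedral mesh of the synthetic rudiment
#'
#' Voxelises the parametric solid on a uniform grid of spacing
#' `target_edge_length`, splits each occupied voxel into six tetrahedra
#' (Kuhn/Freudenthal subdivision, conforming across the grid), then snaps the
#' mesh surface onto the analytic surface of the solid so curved regions are
#' rendered smoothly and the discrete volume tracks the closed-form volume of
#' the generating primitives. Every element carries a region label (MC, PQ,
#' CH or interzone); the mesh also carries the joint-line and retroarticular
#' landmarks and the four muscle attachment points (am, ima, imp, ih) used by
#' the jaw-motion model. Construction is deterministic; `seed` is recorded in
#' the mesh for provenance but no randomness is consumed.
#'
#' @param spec A [rudiment_spec()].
#' @param seed Integer seed recorded with the mesh.
#' @return A `labelled_tet_mesh`: list with `nodes` (N x 3, um), `elems`
#'   (E x 4 node indices, positively oriented), `region` (integer per
#'   element), `region_labels`, `landmarks`, `attachments`, `frame`, `h`,
#'   `spec` and `analytic_volume`.
#' @export
build_rudiment_mesh <- function(spec = rudiment_spec(), seed = 1L) {
  validate_rudiment_spec(spec)
  h <- spec$target_edge_length
  d <- spec$derived
  pad <- h
  ymax <- max(d$pq_half, spec$joint_head_radius,
              abs(spec$ch_anchor_offset[2]) + d$ch_halfwidth)
  # anchor the lattice so the planar region interfaces (the interzone faces
  # at x = +-gap/2 and the PQ faces at y,z = +-pq_half) fall on voxel faces
  anchor <- c(d$g2, -d$pq_half, -d$pq_half)
  raw_lo <- c(min(d$pq_x0, d$ch_x0), -ymax,
              min(d$ch_zbot, -spec$joint_head_radius)) - pad
  raw_hi <- c(d$x_tip, ymax, max(spec$joint_head_radius, d$pq_half)) + pad
  lo <- anchor - h * ceiling((anchor - raw_lo) / h)
  hi <- anchor + h * ceiling((raw_hi - anchor) / h)
  nx <- round((hi[1] - lo[1]) / h)
  ny <- round((hi[2] - lo[2]) / h)
  nz <- round((hi[3] - lo[3]) / h)

  ind <- region_indicators(spec)
  # voxel centres
  cx <- lo[1] + h * (seq_len(nx) - 0.5)
  cy <- lo[2] + h * (seq_len(ny) - 0.5)
  cz <- lo[3] + h * (seq_len(nz) - 0.5)
  centres <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  lab <- integer(nrow(centres))
  for (r in seq_along(ind)) {
    hit <- ind[[r]](centres)
    lab[lab == 0L & hit] <- r
  }
  keep <- which(lab > 0L)
  if (!length(keep)) stop("meshing failure: no voxel centres fall inside the solid; check target_edge_length")

  # voxel integer coordinates (0-based)
  ii <- (keep - 1L) %% nx
  jj <- ((keep - 1L) %/% nx) %% ny
  kk <- (keep - 1L) %/% (nx * ny)

  vid <- function(i, j, k) 1 + i + (nx + 1) * (j + (ny + 1) * k)
  corner <- function(di, dj, dk) vid(ii + di, jj + dj, kk + dk)
  v <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0), corner(1, 1, 0),
             corner(0, 0, 1), corner(1, 0, 1), corner(0, 1, 1), corner(1, 1, 1))
  # Kuhn subdivision: six tets sharing the main diagonal c000-c111
  paths <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  nvox <- length(keep)
  elems_glob <- matrix(0L, nvox * 6L, 4L)
  region <- integer(nvox * 6L)
  for (t in 1:6) {
    rows <- seq.int(t, by = 6L, length.out = nvox)
    elems_glob[rows, ] <- v[, paths[t, ]]
    region[rows] <- lab[keep]
  }

  used <- sort(unique(as.vector(elems_glob)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems_glob], ncol = 4)
  gi <- (used - 1L) %% (nx + 1L)
  gj <- ((used - 1L) %/% (nx + 1L)) %% (ny + 1L)
  gk <- (used - 1L) %/% ((nx + 1L) * (ny + 1L))
  nodes <- cbind(lo[1] + h * gi, lo[2] + h * gj, lo[3] + h * gk)

  # fix orientation (positive volumes)
  vol <- tet_volumes(nodes, elems)
  neg <- vol < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]

  mesh <- list(nodes = nodes, elems = elems, region = region,
               region_labels = names(ind), h = h, spec = spec, seed = seed)
  class(mesh) <- "labelled_tet_mesh"
  mesh <- snap_surface(mesh)

  if (min(tet_volumes(mesh$nodes, mesh$elems)) <= 0) {
    stop("meshing failure: degenerate elements after surface snapping")
  }

  d <- spec$derived
  mesh$frame <- spec$anatomical_frame
  mesh$landmarks <- list(
    joint_centre = c(0, 0, 0),
    joint_line_dir = c(0, 1, 0),
    retroarticular = nearest_node_point(mesh, c(d$xc, 0, -spec$joint_head_radius))
  )
  mesh$attachments <- default_attachments(mesh)
  mesh$analytic_volume <- analytic_region_volumes(spec)
  mesh
}

#' @noRd
nearest_node_point <- function(mesh, p) {
  i <- which.min(colSums((t(mesh$nodes) - p)^2))
  mesh$nodes[i, ]
}

#' @noRd
nearest_node_id <- function(nodes, p) {
  which.min(colSums((t(nodes) - p)^2))
}

# Muscle attachment points and fixed load directions. am drives closure
# (dorsal MC near the joint head, pulling dorso-posteriorly); ima/imp drive
# opening through the retroarticular lever (ventral MC just anterior of the
# joint, pulling posteriorly and slightly ventrally), ih acts on the
# ceratohyal. Opening and closure both carry a posterior component pressing
# the MC head into the interzone, so the cycle-averaged hydrostatic stress at
# the joint is predominantly compressive while the ventrodorsal bending
# gradient reverses sign between the phases -- the loading regime observed in
# the motion simulations on the imaged jaws.
#' @noRd
default_attachments <- function(mesh) {
  spec <- mesh$spec
  d <- spec$derived
  g2 <- d$g2
  R <- spec$joint_head_radius
  pts <- rbind(
    am  = c(d$xc + 0.9 * R, 0, 0.8 * R),
    ima = c(d$xc + 0.2 * R, 0, -0.95 * R),
    imp = c(d$xc + 0.5 * R, 0, -0.9 * R),
    ih  = c((d$ch_x0 + d$ch_x1) / 2, spec$ch_anchor_offset[2], d$ch_zbot)
  )
  dirs <- rbind(
    am  = c(-0.77, 0, 0.64),
    ima = c(-0.94, 0, -0.34),
    imp = c(-0.94, 0, -0.34),
    ih  = c(0, 0, -1)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  node <- vapply(seq_len(4), function(i) nearest_node_id(mesh$nodes, pts[i, ]), 1L)
  tibble::tibble(
    muscle = rownames(pts),
    phase = c("closure", "opening", "opening", "opening"),
    node = node,
    x = mesh$nodes[node, 1], y = mesh$nodes[node, 2], z = mesh$nodes[node, 3],
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3]
  )
}

#' Signed tetrahedron volumes
#' @param nodes N x 3 node coordinates.
#' @param elems E x 4 node indices.
#' @return Numeric vector of signed volumes (um^3).
#' @export
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  cc <- nodes[elems[, 4], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Total mesh volume
#' @param mesh A `labelled_tet_mesh`.
#' @param region Optional region label to restrict to.
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh, region = NULL) {
  keep <- region_element_mask(mesh, region)
  sum(tet_volumes(mesh$nodes, mesh$elems[keep, , drop = FALSE]))
}

#' @noRd
region_element_mask <- function(mesh, region = NULL) {
  if (is.null(region)) return(rep(TRUE, nrow(mesh$elems)))
  r <- match(region, mesh$region_labels)
  if (any(is.na(r))) stop("unknown region: ", paste(region[is.na(r)], collapse = ", "))
  mesh$region %in% r
}

#' Boundary triangles of a mesh (or of one region's submesh)
#'
#' Faces that appear exactly once among the element faces form the surface.
#' @param mesh A `labelled_tet_mesh`.
#' @param region Optional region label(s); the surface of that submesh.
#' @return Integer matrix F x 3 of node indices.
#' @export
boundary_faces <- function(mesh, region = NULL) {
  el <- mesh$elems[region_element_mask(mesh, region), , drop = FALSE]
  f <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)], el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  a <- pmin(f[, 1], f[, 2], f[, 3])
  cmax <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - cmax
  m <- max(f) + 1
  key <- (a * m + b) * m + cmax   # < 2^53 for meshes of this size
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  f[once, , drop = FALSE]
}

#' @noRd
region_nodes <- function(mesh, region) {
  sort(unique(as.vector(mesh$elems[region_element_mask(mesh, region), ])))
}

#' @noRd
surface_nodes <- function(mesh, region = NULL) {
  sort(unique(as.vector(boundary_faces(mesh, region))))
}

# Signed-distance-like field of the union solid: max-combined primitive
# fields per region, min across regions. Not an exact Euclidean distance for
# the tapered rod, but its zero level set is the exact surface, which is all
# the Newton projection below needs.
#' @noRd
solid_levelset <- function(spec) {
  d <- spec$derived
  R <- spec$joint_head_radius
  prof <- spec$mc_radius_profile
  g2 <- d$g2
  function(p) {
    x <- p[, 1]; rho <- sqrt(p[, 2]^2 + p[, 3]^2)
    f_head <- pmax(sqrt((x - d$xc)^2 + rho^2) - R, g2 - x, x - d$x_neck)
    f_rod <- pmax(rho - prof(pmin(pmax(x - g2, d$x_neck - g2), spec$mc_length)),
                  d$x_neck - x, x - d$x_tip)
    f_pq <- pmax(d$pq_x0 - x, x - d$pq_x1,
                 abs(p[, 2]) - d$pq_half, abs(p[, 3]) - d$pq_half)
    f_ch <- pmax(d$ch_x0 - x, x - d$ch_x1,
                 abs(p[, 2] - spec$ch_anchor_offset[2]) - d$ch_halfwidth,
                 p[, 3] - d$ch_ztop, d$ch_zbot - p[, 3])
    f_iz <- pmax(abs(x) - g2, rho - d$iz_radius)
    pmin(f_head, f_rod, f_pq, f_ch, f_iz)
  }
}

# Newton projection of mesh-boundary nodes onto the analytic surface,
# displacement clamped to 0.45 h; backed off geometrically until no element
# inverts.
#' @noRd
snap_surface <- function(mesh) {
  f <- solid_levelset(mesh$spec)
  bn <- surface_nodes(mesh)
  p <- mesh$nodes[bn, , drop = FALSE]
  eps <- 1e-4
  move <- matrix(0, nrow(p), 3)
  q <- p
  for (it in 1:3) {
    f0 <- f(q)
    gx <- (f(q + rep(c(eps, 0, 0), each = nrow(q))) - f0) / eps
    gy <- (f(q + rep(c(0, eps, 0), each = nrow(q))) - f0) / eps
    gz <- (f(q + rep(c(0, 0, eps), each = nrow(q))) - f0) / eps
    g2n <- pmax(gx^2 + gy^2 + gz^2, 1e-12)
    step <- cbind(-f0 * gx / g2n, -f0 * gy / g2n, -f0 * gz / g2n)
    q <- q + step
  }
  move <- q - p
  len <- sqrt(rowSums(move^2))
  cap <- 0.75 * mesh$h
  shrink <- pmin(1, cap / pmax(len, 1e-12))
  move <- move * shrink
  scale <- rep(1, length(bn))
  node_rows <- integer(nrow(mesh$nodes))
  node_rows[bn] <- seq_along(bn)
  qmin <- 0.05 * mesh$h^3 / 6   # quality floor: no sliver below 5% of a
                                # regular subdivision tet's volume
  for (try in 1:12) {
    nodes <- mesh$nodes
    nodes[bn, ] <- p + scale * move
    vol <- tet_volumes(nodes, mesh$elems)
    bad <- vol <= qmin
    if (!any(bad)) {
      mesh$nodes <- nodes
      return(mesh)
    }
    # back off only the nodes of inverted elements
    bad_nodes <- unique(as.vector(mesh$elems[bad, ]))
    rows <- node_rows[bad_nodes]
    rows <- rows[rows > 0]
    scale[rows] <- scale[rows] / 2
  }
  mesh$nodes[bn, ] <- p  # give up snapping; staircase surface retained
  mesh
}

#' @export
print.labelled_tet_mesh <- function(x, ...) {
  cat("<labelled_tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elems),
      " tets, h = ", x$h, " um\n", sep = "")
  tab <- table(factor(x$region_labels[x$region], levels = x$region_labels))
  print(tab)
  invisible(x)
}
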
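# Linear-elastic 4-node tetrahedral finite elements in the um / nN / s unit
# system (stress unit nN/um^2 = kPa, so the nanoindentation moduli and
# muscle forces are usable verbatim). Constant-strain elements with nodal
# volume-averaged stress recovery; uniform-strain patch states are exact.

#' Per-region isotropic elastic material model
#'
#' Cartilaginous regions share one Young's modulus; the interzone is a soft
#' isotropic solid whose modulus is a small fraction of the cartilage value
#' (0.025 percent by default).
#'
#' @param E_cartilage Cartilage Young's modulus (kPa); 142.01 kPa is the
#'   free-to-move nanoindentation value.
#' @param nu Poisson's ratio (all regions).
#' @param interzone_fraction Interzone modulus as a fraction of cartilage.
#' @param region_labels Region label set of the target mesh.
#' @return A `material_model`: tibble with per-region E (kPa) and nu.
#' @export
material_model <- function(E_cartilage = 142.01, nu = 0.3,
                           interzone_fraction = 0.025 / 100,
                           region_labels = c("MC", "PQ", "CH", "interzone")) {
  if (E_cartilage <= 0) stop("Young's modulus must be positive")
  if (nu <= 0 || nu >= 0.5) stop("Poisson ratio must lie in (0, 0.5)")
  if (interzone_fraction <= 0) stop("interzone_fraction must be positive")
  E <- ifelse(region_labels == "interzone",
              interzone_fraction * E_cartilage, E_cartilage)
  out <- tibble::tibble(region = region_labels, E = E, nu = nu)
  attr(out, "interzone_fraction") <- interzone_fraction
  class(out) <- c("material_model", class(out))
  out
}

#' @noRd
lame_parameters <- function(materials, mesh) {
  E <- materials$E[match(mesh$region_labels[mesh$region], materials$region)]
  nu <- materials$nu[match(mesh$region_labels[mesh$region], materials$region)]
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# Shape-function gradients and volumes for all elements.
# grads: list of 4 matrices (E x 3); grads[[a]][e, i] = d(phi_a)/d(x_i).
#' @noRd
element_gradients <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - p1
  b <- nodes[elems[, 3], , drop = FALSE] - p1
  cc <- nodes[elems[, 4], , drop = FALSE] - p1
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bc <- cr(b, cc); ca <- cr(cc, a); ab <- cr(a, b)
  det <- rowSums(a * bc)            # 6V
  g2 <- bc / det; g3 <- ca / det; g4 <- ab / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), V = det / 6)
}

#' Assemble the global stiffness matrix
#' @param mesh A `labelled_tet_mesh`.
#' @param materials A [material_model()].
#' @return Sparse symmetric stiffness (3N x 3N), dof order (node-1)*3 + axis.
#' @export
assemble_stiffness <- function(mesh, materials) {
  lam <- lame_parameters(materials, mesh)
  eg <- element_gradients(mesh$nodes, mesh$elems)
  V <- eg$V
  ne <- length(V)
  iL <- vector("list", 144); jL <- vector("list", 144); xL <- vector("list", 144)
  idx <- 1
  for (aa in 1:4) for (bb in 1:4) {
    ga <- eg$g[[aa]]; gb <- eg$g[[bb]]
    dof_a <- (mesh$elems[, aa] - 1L) * 3L
    dof_b <- (mesh$elems[, bb] - 1L) * 3L
    gg <- rowSums(ga * gb)
    for (i in 1:3) for (j in 1:3) {
      k <- V * (lam$lambda * ga[, i] * gb[, j] + lam$mu * ga[, j] * gb[, i] +
                  if (i == j) lam$mu * gg else 0)
      iL[[idx]] <- dof_a + i; jL[[idx]] <- dof_b + j; xL[[idx]] <- k
      idx <- idx + 1
    }
  }
  Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                       dims = c(3 * nrow(mesh$nodes), 3 * nrow(mesh$nodes)))
}

#' Boundary-condition set
#'
#' @param constraints List of `list(nodes = <ids>, axes = <subset of 1:3>)`.
#' @param n_nodes Number of mesh nodes.
#' @return A `bc_set` with the constrained dof index vector.
#' @export
bc_set <- function(constraints, n_nodes) {
  fixed <- unique(unlist(lapply(constraints, function(cs) {
    as.vector(outer((cs$nodes - 1L) * 3L, cs$axes, "+"))
  })))
  full <- vapply(constraints, function(cs) length(cs$axes) == 3L, TRUE)
  if (!any(full)) stop("at least one node must be constrained in all axes")
  structure(list(constraints = constraints, fixed_dofs = sort(fixed),
                 n_nodes = n_nodes), class = "bc_set")
}

#' Physiological boundary conditions of the jaw model
#'
#' The anterior end of the ceratohyal is fixed in all directions; only
#' anteroposterior translations of the posterior end of the palatoquadrate
#' are allowed; mediolateral translations of the anterior end of the
#' Meckel's cartilage are prevented (midsagittal symmetry of the missing
#' half-jaw).
#'
#' @param mesh A `labelled_tet_mesh` from [build_rudiment_mesh()].
#' @return A `bc_set`.
#' @export
default_jaw_bcs <- function(mesh) {
  nd <- mesh$nodes
  ch <- region_nodes(mesh, "CH")
  ch_ant <- ch[nd[ch, 1] >= max(nd[ch, 1]) - mesh$h - 1e-9]
  pq <- region_nodes(mesh, "PQ")
  pq_post <- pq[nd[pq, 1] <= min(nd[pq, 1]) + 1e-9]
  mc <- region_nodes(mesh, "MC")
  mc_ant <- mc[nd[mc, 1] >= max(nd[mc, 1]) - 1e-9]
  bc_set(list(list(nodes = ch_ant, axes = 1:3),
              list(nodes = pq_post, axes = 2:3),
              list(nodes = mc_ant, axes = 2L)),
         nrow(nd))
}

# Minimal statically determinate 3-2-1 pinning for growth solves: the node
# nearest the joint centre is fixed, ML/VD of an on-axis anterior node and
# VD of a lateral node remove the rotations. Because the set is statically
# determinate the pinned solution equals the free (self-equilibrated)
# solution plus a linearised rigid motion, which the caller removes by a
# joint-anchored rigid fit.
#' @noRd
growth_pin_bcs <- function(mesh) {
  o <- mesh$landmarks$joint_centre
  n0 <- nearest_node_id(mesh$nodes, o)
  x <- sweep(mesh$nodes, 2, o)
  ax <- which(abs(x[, 2]) + abs(x[, 3]) < 4 & x[, 1] > 10)
  if (!length(ax)) ax <- which.max(x[, 1])
  n1 <- ax[which.max(x[ax, 1])]
  side <- setdiff(which(abs(x[, 1]) + abs(x[, 3]) < 4), c(n0, n1))
  if (!length(side)) side <- setdiff(seq_len(nrow(x)), c(n0, n1))
  n2 <- side[which.max(abs(x[side, 2]))]
  bc_set(list(list(nodes = n0, axes = 1:3),
              list(nodes = n1, axes = 2:3),
              list(nodes = n2, axes = 3L)),
         nrow(mesh$nodes))
}

#' Solve the linear elastostatic problem
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param materials A [material_model()].
#' @param bcs A [bc_set()] (homogeneous constraints).
#' @param loads Either a tibble with columns `node`, `fx`, `fy`, `fz`
#'   (point loads, nN) or a full force vector of length 3N.
#' @param load_factor Scalar multiplier on the loads.
#' @param stiffness Optional pre-assembled stiffness (reused across solves).
#' @return List with `u` (N x 3 displacements, um), `stress_nodes` (N x 6
#'   Voigt xx,yy,zz,xy,yz,xz, kPa), `stress_elems` (E x 6), `sigma_h`
#'   (per-node hydrostatic stress, kPa).
#' @export
solve_elasticity <- function(mesh, materials, bcs, loads, load_factor = 1,
                             stiffness = NULL) {
  n <- nrow(mesh$nodes)
  F <- numeric(3 * n)
  if (is.numeric(loads) && length(loads) == 3 * n) {
    F <- loads
  } else {
    stopifnot(all(c("node", "fx", "fy", "fz") %in% names(loads)))
    for (r in seq_len(nrow(loads))) {
      d <- (loads$node[r] - 1L) * 3L
      F[d + 1] <- F[d + 1] + loads$fx[r]
      F[d + 2] <- F[d + 2] + loads$fy[r]
      F[d + 3] <- F[d + 3] + loads$fz[r]
    }
  }
  F <- F * load_factor
  if (is.null(stiffness)) stiffness <- assemble_stiffness(mesh, materials)
  free <- setdiff(seq_len(3 * n), bcs$fixed_dofs)
  K <- Matrix::forceSymmetric(stiffness[free, free, drop = FALSE])
  uf <- tryCatch(
    as.numeric(Matrix::solve(K, F[free])),
    error = function(e) stop("elastic solve failed (singular system? ",
                             conditionMessage(e), ")"))
  u <- numeric(3 * n); u[free] <- uf
  res <- as.numeric(stiffness %*% u - F)
  res[bcs$fixed_dofs] <- 0
  fn <- sqrt(sum(F[free]^2))
  if (fn > 0 && sqrt(sum(res^2)) > 1e-6 * fn) {
    stop("elastic solve did not reach equilibrium (relative residual ",
         signif(sqrt(sum(res^2)) / fn, 3), ")")
  }
  u <- matrix(u, ncol = 3, byrow = TRUE)
  st <- recover_stresses(mesh, materials, u)
  c(list(u = u), st)
}

#' @noRd
recover_stresses <- function(mesh, materials, u) {
  lam <- lame_parameters(materials, mesh)
  eg <- element_gradients(mesh$nodes, mesh$elems)
  ex <- eyy <- ezz <- exy <- eyz <- exz <- 0
  for (aa in 1:4) {
    ua <- u[mesh$elems[, aa], , drop = FALSE]
    g <- eg$g[[aa]]
    ex <- ex + ua[, 1] * g[, 1]
    eyy <- eyy + ua[, 2] * g[, 2]
    ezz <- ezz + ua[, 3] * g[, 3]
    exy <- exy + 0.5 * (ua[, 1] * g[, 2] + ua[, 2] * g[, 1])
    eyz <- eyz + 0.5 * (ua[, 2] * g[, 3] + ua[, 3] * g[, 2])
    exz <- exz + 0.5 * (ua[, 1] * g[, 3] + ua[, 3] * g[, 1])
  }
  tr <- ex + eyy + ezz
  se <- cbind(xx = lam$lambda * tr + 2 * lam$mu * ex,
              yy = lam$lambda * tr + 2 * lam$mu * eyy,
              zz = lam$lambda * tr + 2 * lam$mu * ezz,
              xy = 2 * lam$mu * exy,
              yz = 2 * lam$mu * eyz,
              xz = 2 * lam$mu * exz)
  sn <- node_average(mesh, se, eg$V)
  list(stress_elems = se, stress_nodes = sn,
       sigma_h = rowSums(sn[, 1:3]) / 3)
}

# volume-weighted element-to-node averaging
#' @noRd
node_average <- function(mesh, evals, V = NULL) {
  if (is.null(V)) V <- tet_volumes(mesh$nodes, mesh$elems)
  n <- nrow(mesh$nodes)
  wsum <- numeric(n)
  out <- matrix(0, n, ncol(evals))
  for (aa in 1:4) {
    idx <- mesh$elems[, aa]
    wsum <- wsum + unname(tapply_add(V, idx, n))
    for (c1 in seq_len(ncol(evals))) {
      out[, c1] <- out[, c1] + tapply_add(V * evals[, c1], idx, n)
    }
  }
  out / wsum
}

#' @noRd
tapply_add <- function(x, idx, n) {
  v <- numeric(n)
  rs <- rowsum(x, idx)
  v[as.integer(rownames(rs))] <- rs[, 1]
  v
}

#' Consistent nodal forces for a uniform traction on boundary triangles
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param faces F x 3 node-index matrix (subset of [boundary_faces()]).
#' @param traction 3-vector, force per unit area (kPa).
#' @return Force vector of length 3N (nN).
#' @export
traction_loads <- function(mesh, faces, traction) {
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  n <- nrow(mesh$nodes)
  F <- numeric(3 * n)
  for (a in 1:3) {
    for (i in 1:3) {
      F[(seq_len(n) - 1L) * 3L + i] <- F[(seq_len(n) - 1L) * 3L + i] +
        tapply_add(area / 3 * traction[i], faces[, a], n)
    }
  }
  F
}

#' Hydrostatic stress of a stress tensor
#'
#' One third of the trace; compression is negative under the
#' tension-positive convention used throughout.
#'
#' @param stress Either a 3x3 symmetric tensor or an n x 6 Voigt matrix
#'   (xx, yy, zz, ...).
#' @return Scalar or vector of hydrostatic stress (kPa).
#' @export
hydrostatic <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 3 && nrow(stress) == 3) {
    return(sum(diag(stress)) / 3)
  }
  rowSums(stress[, 1:3, drop = FALSE]) / 3
}
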
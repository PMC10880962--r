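#' Muscle point-load set for the jaw-motion model
#'
#' Point loads in fixed directions at the mesh's muscle attachment points:
#' the adductor mandibularis (am) drives closure; the intermandibularis
#' anterior/posterior (ima, imp) and interhyal (ih) drive opening. Default
#' magnitudes are the 4 dpf physiological-movement forces; the 4.5 dpf set is
#' available via `age`.
#'
#' @param mesh A `labelled_tet_mesh` with attachment points.
#' @param forces Named magnitudes in nN (am, ima, imp, ih).
#' @param age Convenience switch: `4` or `4.5` picks the published force set
#'   for that age (ignored if `forces` is given).
#' @return A `muscle_load_set` tibble: muscle, phase, node, direction,
#'   magnitude.
#' @export
muscle_load_set <- function(mesh, forces = NULL, age = 4) {
  if (is.null(forces)) {
    forces <- if (age == 4) c(am = 2.84, ima = 1.25, imp = 1.50, ih = 1.50)
              else c(am = 4.35, ima = 2.90, imp = 3.47, ih = 3.47)
  }
  at <- mesh$attachments
  stopifnot(all(at$muscle %in% names(forces)))
  out <- dplyr::mutate(at, magnitude = unname(forces[at$muscle]))
  if (any(out$magnitude < 0)) stop("muscle force magnitudes must be >= 0")
  nrm <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  if (max(abs(nrm - 1)) > 1e-8) stop("muscle directions must be unit norm")
  class(out) <- c("muscle_load_set", class(out))
  out
}

# Each muscle force is distributed uniformly over the attachment patch (the
# surface nodes within `radius` of the attachment point): muscles attach
# over an area, and point loads on a single node would leave an artificial
# stress singularity in the hydrostatic fields the growth laws consume.
#' @noRd
phase_point_loads <- function(loads, phase, scale = 1, mesh = NULL,
                              radius = 2.5) {
  d <- loads[loads$phase == phase, ]
  if (is.null(mesh)) {
    return(tibble::tibble(node = d$node,
                          fx = scale * d$magnitude * d$dx,
                          fy = scale * d$magnitude * d$dy,
                          fz = scale * d$magnitude * d$dz))
  }
  surf <- surface_nodes(mesh)
  rows <- vector("list", nrow(d))
  for (r in seq_len(nrow(d))) {
    p <- mesh$nodes[d$node[r], ]
    patch <- surf[colSums((t(mesh$nodes[surf, , drop = FALSE]) - p)^2) <=
                    radius^2]
    if (!length(patch)) patch <- d$node[r]
    rows[[r]] <- tibble::tibble(
      node = patch,
      fx = scale * d$magnitude[r] * d$dx[r] / length(patch),
      fy = scale * d$magnitude[r] * d$dy[r] / length(patch),
      fz = scale * d$magnitude[r] * d$dz[r] / length(patch))
  }
  dplyr::bind_rows(rows)
}

#' Simulate one quasi-static jaw closure + opening cycle
#'
#' Closure loads are ramped from zero to full over `n_increments` increments,
#' then released and the opening loads ramped likewise (sequential steps).
#' The model is geometrically and materially linear, so each increment's
#' field is an exact fraction of the corresponding peak solution. Hydrostatic
#' stress is stored per node for every increment.
#'
#' @param mesh,materials,bcs Model definition.
#' @param loads A [muscle_load_set()].
#' @param n_increments Increments per step (default 5, as in the source
#'   motion simulations).
#' @param scale Scalar multiplier applied to every muscle force (e.g. from
#'   [calibrate_muscle_forces()]).
#' @return A `stress_history`: list with `increments` (list of per-node
#'   sigma_h vectors, length 2 * n_increments), `peak_closure`,
#'   `peak_opening`, the peak solutions, and the opening tip displacement.
#' @export
simulate_jaw_cycle <- function(mesh, materials, bcs, loads,
                               n_increments = 5, scale = 1) {
  stopifnot(n_increments >= 1)
  K <- assemble_stiffness(mesh, materials)
  sol_close <- solve_elasticity(mesh, materials, bcs,
                                phase_point_loads(loads, "closure", scale,
                                                  mesh),
                                stiffness = K)
  sol_open <- solve_elasticity(mesh, materials, bcs,
                               phase_point_loads(loads, "opening", scale,
                                                 mesh),
                               stiffness = K)
  increments <- c(lapply(seq_len(n_increments) / n_increments,
                         function(f) f * sol_close$sigma_h),
                  lapply(seq_len(n_increments) / n_increments,
                         function(f) f * sol_open$sigma_h))
  tip <- mc_tip_node(mesh)
  structure(list(increments = increments,
                 n_increments_per_step = n_increments,
                 peak_closure = n_increments,
                 peak_opening = 2L * n_increments,
                 sol_close = sol_close, sol_open = sol_open,
                 tip_node = tip,
                 opening_displacement = abs(sol_open$u[tip, 3])),
            class = "stress_history")
}

# anterior-tip node of the MC (max AP, most ventral among ties)
#' @noRd
mc_tip_node <- function(mesh) {
  mc <- region_nodes(mesh, "MC")
  x <- mesh$nodes[mc, 1]
  cand <- mc[x >= max(x) - 1e-9]
  cand[which.min(abs(mesh$nodes[cand, 2]) + abs(mesh$nodes[cand, 3]))]
}

#' Cycle-averaged hydrostatic stress field
#'
#' Arithmetic mean of the per-node hydrostatic stress over all stored
#' increments of the cycle.
#'
#' @param history A `stress_history`.
#' @return Per-node numeric vector (kPa).
#' @export
average_hydrostatic <- function(history) {
  stopifnot(length(history$increments) >= 1)
  Reduce(`+`, history$increments) / length(history$increments)
}

#' Clamp a stress field to its compressive part
#' @param field Numeric vector/matrix (kPa), tension positive.
#' @return `min(field, 0)` elementwise.
#' @export
compressive_clamp <- function(field) {
  pmin(field, 0)
}

#' Nodal gradient of a scalar field on a tet mesh
#'
#' Per node, a least-squares linear fit of the field over the node's
#' edge-connected neighbourhood (including itself); exact for fields linear
#' in position. Nodes with a rank-deficient neighbourhood fall back to the
#' volume-weighted average of the incident elements' constant gradients and
#' are flagged. The gradient is expressed in the anatomical frame as the
#' diagonal (d/dx, d/dy, d/dz) triple used by the gradient growth laws.
#'
#' @param field Per-node numeric vector.
#' @param mesh A `labelled_tet_mesh`.
#' @return N x 3 matrix (kPa/um) with attribute `fallback_nodes`.
#' @export
nodal_gradient <- function(field, mesh) {
  if (!all(is.finite(field))) stop("field must be finite")
  n <- nrow(mesh$nodes)
  el <- mesh$elems
  ed <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
              el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  ed <- unique(rbind(ed, ed[, c(2, 1)]))
  sp <- split(ed[, 2], ed[, 1])
  nb <- vector("list", n)
  nb[as.integer(names(sp))] <- sp
  grad <- matrix(0, n, 3)
  fallback <- logical(n)
  for (v in seq_len(n)) {
    nbr <- c(v, nb[[v]])
    X <- cbind(1, sweep(mesh$nodes[nbr, , drop = FALSE], 2, mesh$nodes[v, ]))
    y <- field[nbr]
    XtX <- crossprod(X)
    ok <- length(nbr) >= 4 && rcond(XtX) > 1e-12
    if (ok) {
      beta <- solve(XtX, crossprod(X, y))
      grad[v, ] <- beta[2:4]
    } else {
      fallback[v] <- TRUE
    }
  }
  if (any(fallback)) {
    eg <- element_gradients(mesh$nodes, mesh$elems)
    ge <- matrix(0, nrow(el), 3)
    for (aa in 1:4) ge <- ge + field[el[, aa]] * eg$g[[aa]]
    gn <- node_average(mesh, ge, eg$V)
    grad[fallback, ] <- gn[fallback, , drop = FALSE]
  }
  attr(grad, "fallback_nodes") <- which(fallback)
  grad
}

#' Calibrate muscle forces to a physiological jaw opening
#'
#' Scales the opening-phase muscle forces (fixed published ratios) so the
#' ventrodorsal displacement of the MC anterior tip at peak opening equals
#' the target (37.2 um, the average jaw displacement of 5 dpf larvae). The
#' model is linear, so the scale is the closed-form ratio of target to unit
#' response; the achieved opening is re-measured at the returned scale.
#'
#' @param mesh,materials,bcs Model definition.
#' @param loads A [muscle_load_set()] carrying the force ratios.
#' @param target_opening Target VD tip displacement (um).
#' @return List with `scale`, `achieved_opening`, `tip_node`.
#' @export
calibrate_muscle_forces <- function(mesh, materials, bcs, loads,
                                    target_opening = 37.2) {
  stopifnot(target_opening > 0)
  K <- assemble_stiffness(mesh, materials)
  sol1 <- solve_elasticity(mesh, materials, bcs,
                           phase_point_loads(loads, "opening", 1, mesh),
                           stiffness = K)
  tip <- mc_tip_node(mesh)
  unit_resp <- abs(sol1$u[tip, 3])
  if (unit_resp < 1e-12) stop("zero opening response at the MC tip; check loads/BCs")
  scale <- target_opening / unit_resp
  sol2 <- solve_elasticity(mesh, materials, bcs,
                           phase_point_loads(loads, "opening", scale, mesh),
                           stiffness = K)
  list(scale = scale, achieved_opening = abs(sol2$u[tip, 3]), tip_node = tip)
}
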
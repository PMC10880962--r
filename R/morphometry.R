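#' Rigid alignment to the joint-line / retroarticular landmarks
#'
#' Brings a shape into the anatomical frame: the joint-line centre is
#' translated to the origin; the joint-line direction is rotated onto the ML
#' axis; the residual rotation about ML is fixed by mapping the
#' joint-to-retroarticular direction into the VD-AP plane at its reference
#' orientation (the retroarticular process sits ventrally and slightly
#' anterior of the joint). With the joint-line direction supplied the
#' transform recovers an arbitrary rigid motion exactly; without it, the
#' minimal rotation taking the retroarticular direction to its reference is
#' used (exact for in-plane motions).
#'
#' @param shape A `labelled_tet_mesh`, `shape_stack`, or n x 3 matrix.
#' @param joint_line Joint-line centre (3-vector).
#' @param retroarticular Retroarticular process position (3-vector).
#' @param frame Anatomical frame of the target space.
#' @param joint_line_dir Optional joint-line direction (ML line through the
#'   joint). Meshes carry this landmark.
#' @param ref_direction Reference unit direction of joint-to-retroarticular
#'   in the aligned frame.
#' @return List with `shape` (aligned), `rotation` (3x3), `translation`
#'   (applied after rotation), and `transform` (4x4 homogeneous).
#' @export
align_to_landmarks <- function(shape, joint_line, retroarticular,
                               frame = default_frame(),
                               joint_line_dir = NULL,
                               ref_direction = c(5, 0, -10) / sqrt(125)) {
  if (max(abs(joint_line - retroarticular)) < 1e-12) {
    stop("joint-line and retroarticular landmarks coincide")
  }
  d_retro <- retroarticular - joint_line
  d_retro <- d_retro / sqrt(sum(d_retro^2))
  if (!is.null(joint_line_dir)) {
    b1 <- joint_line_dir / sqrt(sum(joint_line_dir^2))
    b2 <- d_retro - sum(d_retro * b1) * b1
    if (sqrt(sum(b2^2)) < 1e-9) stop("retroarticular lies on the joint line")
    b2 <- b2 / sqrt(sum(b2^2))
    B_src <- cbind(b1, b2, vcross(b1, b2))
    t1 <- frame["ML", ]
    t2 <- ref_direction - sum(ref_direction * t1) * t1
    t2 <- t2 / sqrt(sum(t2^2))
    B_tgt <- cbind(t1, t2, vcross(t1, t2))
    R <- B_tgt %*% t(B_src)
  } else {
    R <- rotation_between(d_retro, ref_direction)
  }
  pts <- shape_points(shape)
  newpts <- sweep(pts, 2, joint_line) %*% t(R)
  out <- set_shape_points(shape, newpts)
  if (inherits(out, "labelled_tet_mesh")) {
    out$landmarks$joint_centre <- c(0, 0, 0)
    out$landmarks$retroarticular <-
      drop(R %*% (retroarticular - joint_line))
    if (!is.null(joint_line_dir)) {
      out$landmarks$joint_line_dir <- drop(R %*% joint_line_dir)
    }
  }
  transform <- rbind(cbind(R, -R %*% joint_line), c(0, 0, 0, 1))
  list(shape = out, rotation = R, translation = drop(-R %*% joint_line),
       transform = transform)
}

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# minimal rotation taking unit vector a to unit vector b (Rodrigues)
#' @noRd
rotation_between <- function(a, b) {
  v <- vcross(a, b); c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-14) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) vcross(a, c(1, 0, 0)) else vcross(a, c(0, 1, 0))
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' @noRd
shape_points <- function(shape) {
  if (inherits(shape, "labelled_tet_mesh")) return(shape$nodes)
  if (inherits(shape, "shape_stack")) {
    return(stack_points_3d(shape))
  }
  as.matrix(shape)
}

#' @noRd
set_shape_points <- function(shape, pts) {
  if (inherits(shape, "labelled_tet_mesh")) {
    shape$nodes <- pts
    return(shape)
  }
  if (inherits(shape, "shape_stack")) {
    return(stack_from_points_3d(shape, pts))
  }
  pts
}

#' Stack of closed transversal outlines
#'
#' A `shape_stack` holds closed 2D outlines (polylines in the ML-VD plane) at
#' strictly increasing AP slice positions; the representation the average
#' shapes are built in.
#'
#' @param df Tibble with columns `slice`, `axial_pos`, `point`, `u` (ML), `v`
#'   (VD).
#' @param frame Anatomical frame.
#' @return A `shape_stack`.
#' @export
shape_stack <- function(df, frame = default_frame()) {
  need <- c("slice", "axial_pos", "point", "u", "v")
  stopifnot(all(need %in% names(df)))
  pos <- unique(df[, c("slice", "axial_pos")])
  pos <- pos[order(pos$slice), ]
  if (any(diff(pos$axial_pos) <= 0)) {
    stop("slice positions must be strictly increasing")
  }
  structure(tibble::as_tibble(df), frame = frame,
            class = c("shape_stack", class(tibble::tibble())))
}

#' @noRd
stack_points_3d <- function(st) {
  cbind(st$axial_pos, st$u, st$v)
}

#' @noRd
stack_from_points_3d <- function(st, pts) {
  st$axial_pos <- pts[, 1]; st$u <- pts[, 2]; st$v <- pts[, 3]
  st
}

#' Cross-section outlines of a mesh region
#'
#' Slices the region at `n_slices` AP positions; each outline is the polar
#' (max-radius per angle about the slice centroid) boundary of the plane
#' intersection with the region's tetrahedra, resampled at `n_points` uniform
#' angles. Adequate for the convex, roughly tubular sections of these
#' rudiments; strongly non-star-shaped sections would need a different
#' correspondence rule.
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param region Region label.
#' @param n_slices,n_points Resolution of the stack.
#' @return A `shape_stack`.
#' @export
mesh_to_shape_stack <- function(mesh, region = "MC", n_slices = 20,
                                n_points = 72) {
  el <- mesh$elems[region_element_mask(mesh, region), , drop = FALSE]
  nd <- mesh$nodes
  xr <- range(nd[unique(as.vector(el)), 1])
  pos <- seq(xr[1] + 1e-6 * diff(xr), xr[2] - 1e-6 * diff(xr),
             length.out = n_slices)
  ang <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  edges <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  x1 <- nd[edges[, 1], 1]; x2 <- nd[edges[, 2], 1]
  rows <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    x0 <- pos[s]
    hit <- (x1 - x0) * (x2 - x0) <= 0 & abs(x2 - x1) > 1e-12
    t <- (x0 - x1[hit]) / (x2[hit] - x1[hit])
    py <- nd[edges[hit, 1], 2] + t * (nd[edges[hit, 2], 2] - nd[edges[hit, 1], 2])
    pz <- nd[edges[hit, 1], 3] + t * (nd[edges[hit, 2], 3] - nd[edges[hit, 1], 3])
    if (length(py) < 3) next
    cu <- mean(py); cv <- mean(pz)
    th <- atan2(pz - cv, py - cu)
    r <- sqrt((py - cu)^2 + (pz - cv)^2)
    # max radius per angular bin, interpolated circularly over empty bins
    bin <- pmin(n_points, 1 + floor((th + pi) / (2 * pi) * n_points))
    rb <- rep(NA_real_, n_points)
    agg <- tapply(r, bin, max)
    rb[as.integer(names(agg))] <- agg
    if (anyNA(rb)) {
      idx <- which(!is.na(rb))
      for (b in which(is.na(rb))) {
        d <- pmin(abs(idx - b), n_points - abs(idx - b))
        rb[b] <- rb[idx[which.min(d)]]
      }
    }
    th_b <- -pi + (seq_len(n_points) - 0.5) * 2 * pi / n_points
    rows[[s]] <- tibble::tibble(slice = s, axial_pos = x0,
                                point = seq_len(n_points),
                                u = cu + rb * cos(th_b),
                                v = cv + rb * sin(th_b))
  }
  shape_stack(dplyr::bind_rows(rows), frame = mesh$frame)
}

#' Average shape of aligned outline stacks
#'
#' Each input stack is resampled onto a common set of slice positions
#' spanning the overlapping axial range; each outline is resampled to
#' `n_points` points with angular correspondence about the slice centroid,
#' and the average outline is the pointwise mean.
#'
#' @param shapes List of aligned `shape_stack`s (at least two).
#' @param n_slices,n_points Resolution of the average.
#' @return A `shape_stack`.
#' @export
average_shape <- function(shapes, n_slices = 20, n_points = 72) {
  stopifnot(length(shapes) >= 2)
  rng <- vapply(shapes, function(s) range(s$axial_pos), numeric(2))
  lo <- max(rng[1, ]); hi <- min(rng[2, ])
  if (lo >= hi) stop("shapes have no overlapping axial range")
  pos <- seq(lo, hi, length.out = n_slices)
  acc_u <- matrix(0, n_slices, n_points)
  acc_v <- matrix(0, n_slices, n_points)
  for (sh in shapes) {
    res <- resample_stack(sh, pos, n_points)
    acc_u <- acc_u + res$u; acc_v <- acc_v + res$v
  }
  acc_u <- acc_u / length(shapes); acc_v <- acc_v / length(shapes)
  df <- tibble::tibble(
    slice = rep(seq_len(n_slices), each = n_points),
    axial_pos = rep(pos, each = n_points),
    point = rep(seq_len(n_points), n_slices),
    u = as.vector(t(acc_u)), v = as.vector(t(acc_v)))
  shape_stack(df, frame = attr(shapes[[1]], "frame"))
}

# polar resampling of one stack onto target slice positions
#' @noRd
resample_stack <- function(st, pos, n_points) {
  th_t <- -pi + (seq_len(n_points) - 0.5) * 2 * pi / n_points
  sl <- unique(st[, c("slice", "axial_pos")])
  sl <- sl[order(sl$axial_pos), ]
  per_slice <- lapply(sl$slice, function(s) {
    d <- st[st$slice == s, ]
    cu <- mean(d$u); cv <- mean(d$v)
    th <- atan2(d$v - cv, d$u - cu)
    r <- sqrt((d$u - cu)^2 + (d$v - cv)^2)
    o <- order(th)
    th <- th[o]; r <- r[o]
    th_ext <- c(th - 2 * pi, th, th + 2 * pi)
    r_ext <- c(r, r, r)
    list(cu = cu, cv = cv,
         r = stats::approx(th_ext, r_ext, xout = th_t, rule = 2)$y)
  })
  u <- matrix(0, length(pos), n_points); v <- u
  for (k in seq_along(pos)) {
    i2 <- findInterval(pos[k], sl$axial_pos, all.inside = TRUE)
    lo <- per_slice[[i2]]; hi2 <- per_slice[[min(i2 + 1, length(per_slice))]]
    x0 <- sl$axial_pos[i2]; x1 <- sl$axial_pos[min(i2 + 1, nrow(sl))]
    w <- if (x1 > x0) pmin(1, pmax(0, (pos[k] - x0) / (x1 - x0))) else 0
    cu <- (1 - w) * lo$cu + w * hi2$cu
    cv <- (1 - w) * lo$cv + w * hi2$cv
    r <- (1 - w) * lo$r + w * hi2$r
    u[k, ] <- cu + r * cos(th_t)
    v[k, ] <- cv + r * sin(th_t)
  }
  list(u = u, v = v)
}

#' Crop a shape along the anteroposterior axis
#'
#' Keeps only material within `distance` of the joint line along AP (the
#' joint line is at AP = 0 after alignment, with the MC extending to positive
#' AP).
#'
#' @param shape A `labelled_tet_mesh` or `shape_stack` (aligned).
#' @param distance Crop distance (um), > 0.
#' @return The cropped shape.
#' @export
crop_anteroposterior <- function(shape, distance) {
  if (!is.numeric(distance) || distance <= 0) {
    stop("crop distance must be positive")
  }
  if (inherits(shape, "shape_stack")) {
    keep <- abs(shape$axial_pos) <= distance
    return(shape_stack(shape[keep, ], frame = attr(shape, "frame")))
  }
  if (inherits(shape, "labelled_tet_mesh")) {
    ctr <- (shape$nodes[shape$elems[, 1], 1] + shape$nodes[shape$elems[, 2], 1] +
            shape$nodes[shape$elems[, 3], 1] + shape$nodes[shape$elems[, 4], 1]) / 4
    keep <- abs(ctr - shape$landmarks$joint_centre[1]) <= distance
    out <- shape
    out$elems <- shape$elems[keep, , drop = FALSE]
    out$region <- shape$region[keep]
    return(out)
  }
  pts <- as.matrix(shape)
  pts[abs(pts[, 1]) <= distance, , drop = FALSE]
}

#' Organ-level morphometrics: length, depth, width
#'
#' On an aligned shape: `length` is the AP extent, `depth` the VD extent and
#' `width` the maximal ML extent within `joint_slab` um of the joint line
#' along AP ("width at the level of the joint").
#'
#' @param shape A `labelled_tet_mesh`, `shape_stack`, or n x 3 point matrix.
#' @param region Region to measure when `shape` is a mesh (default MC).
#' @param joint_slab Half-thickness of the AP slab for the width measure
#'   (um); the level of the joint is not quantified in the source data and 5
#'   um is the package default.
#' @param joint_centre AP position of the joint line; taken from mesh
#'   landmarks when available.
#' @return One-row tibble of class `morphometrics` with `length`, `depth`,
#'   `width` (um).
#' @export
measure_morphometrics <- function(shape, region = "MC", joint_slab = 5,
                                  joint_centre = NULL) {
  edges <- NULL
  if (inherits(shape, "labelled_tet_mesh")) {
    ids <- region_nodes(shape, region)
    pts <- shape$nodes[ids, , drop = FALSE]
    edges <- region_edges(shape, region)
    edges <- cbind(match(edges[, 1], ids), match(edges[, 2], ids))
    if (is.null(joint_centre)) joint_centre <- shape$landmarks$joint_centre
  } else if (inherits(shape, "shape_stack")) {
    pts <- stack_points_3d(shape)
  } else {
    pts <- as.matrix(shape)
  }
  if (!nrow(pts)) stop("empty shape")
  if (is.null(joint_centre)) joint_centre <- c(0, 0, 0)
  v <- point_morphometrics(pts, joint_centre, joint_slab, edges)
  out <- tibble::tibble(length = v[["length"]], depth = v[["depth"]],
                        width = v[["width"]])
  class(out) <- c("morphometrics", class(out))
  out
}

#' Percent change between two morphometric measurements
#' @param before,after `morphometrics` tibbles (before values must be > 0).
#' @return One-row tibble with signed percent changes.
#' @export
percent_change <- function(before, after) {
  b <- unlist(before[1, c("length", "depth", "width")])
  a <- unlist(after[1, c("length", "depth", "width")])
  if (any(b <= 0)) stop("baseline morphometrics must be positive")
  tibble::tibble(length = 100 * (a[["length"]] / b[["length"]] - 1),
                 depth = 100 * (a[["depth"]] / b[["depth"]] - 1),
                 width = 100 * (a[["width"]] / b[["width"]] - 1))
}
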
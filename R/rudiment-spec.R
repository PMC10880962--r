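#' Parametric description of the synthetic jaw-joint rudiment
#'
#' The synthetic rudiment is a parametric solid standing in for the segmented
#' larval zebrafish lower jaw: a Meckel's cartilage (MC) element built from a
#' blunt spherical joint head continued by a tapering rod, a palatoquadrate
#' (PQ) block mirrored across the joint, a thin compliant interzone slab
#' bridging the two, and a ceratohyal (CH) anchor bar fused beneath the PQ.
#' All lengths are micrometres. The world frame is anatomical: x points
#' anteriorly (AP), y medio-laterally (ML), z dorsally (VD), with the joint
#' line centred at the origin.
#'
#' @param mc_length Anteroposterior extent of the MC element, from its joint
#'   face to the anterior tip (um).
#' @param mc_radius_profile Function of axial position along the MC rod
#'   (distance anterior of the joint face, um) returning the rod radius (um).
#'   Only evaluated anterior of the spherical head; the default tapers
#'   linearly from the neck radius to 5 um at the tip.
#' @param joint_head_radius Radius of the spherical MC joint head (um).
#' @param interzone_gap Thickness of the interzone slab separating MC and PQ
#'   along AP (um). Must be smaller than `joint_head_radius`.
#' @param pq_length AP extent of the palatoquadrate block (um).
#' @param ch_anchor_offset 3-vector: position of the posterior end of the
#'   ceratohyal anchor bar (um).
#' @param anatomical_frame 3x3 matrix with rows named `AP`, `ML`, `VD`;
#'   orthonormal to 1e-10.
#' @param target_edge_length Requested element edge length (um). The meshes
#'   in the source imaging pipeline used elements of approximately 2 um.
#' @param neck_radius Rod radius where the rod meets the spherical head (um).
#' @param head_offset AP offset of the head-sphere centre anterior of the MC
#'   joint face (um); keeps the joint face a broad disc rather than a point.
#'
#' @return An object of class `rudiment_spec`.
#' @export
rudiment_spec <- function(mc_length = 40,
                          mc_radius_profile = NULL,
                          joint_head_radius = 10,
                          interzone_gap = 6,
                          pq_length = 20,
                          ch_anchor_offset = c(-23, 0, -11),
                          anatomical_frame = default_frame(),
                          target_edge_length = 2,
                          neck_radius = 7,
                          head_offset = 0) {
  spec <- list(
    mc_length = mc_length,
    mc_radius_profile = mc_radius_profile,
    joint_head_radius = joint_head_radius,
    interzone_gap = interzone_gap,
    pq_length = pq_length,
    ch_anchor_offset = ch_anchor_offset,
    anatomical_frame = anatomical_frame,
    target_edge_length = target_edge_length,
    neck_radius = neck_radius,
    head_offset = head_offset
  )
  class(spec) <- "rudiment_spec"
  validate_rudiment_spec(spec)
  # derived geometry, all in the anatomical frame with the joint at origin
  g2 <- interzone_gap / 2
  xc <- g2 + head_offset                      # head sphere centre (AP)
  x_neck <- xc + sqrt(joint_head_radius^2 - neck_radius^2)
  x_tip <- g2 + mc_length
  if (x_neck >= x_tip) {
    stop("mc_length too short for joint_head_radius/neck_radius: ",
         "the spherical head alone spans past the requested tip")
  }
  if (is.null(spec$mc_radius_profile)) {
    s0 <- x_neck - g2
    s1 <- mc_length
    spec$mc_radius_profile <- function(s) {
      t <- pmin(1, pmax(0, (s - s0) / (s1 - s0)))
      neck_radius + t * (5 - neck_radius)
    }
  }
  spec$derived <- list(
    g2 = g2, xc = xc, x_neck = x_neck, x_tip = x_tip,
    iz_radius = 0.8 * joint_head_radius,
    pq_half = 0.9 * joint_head_radius,
    pq_x0 = -g2 - pq_length, pq_x1 = -g2,
    ch_halfwidth = 4, ch_thickness = 4,
    ch_x0 = ch_anchor_offset[1], ch_x1 = -g2 - 3,
    ch_ztop = -0.9 * joint_head_radius
  )
  spec$derived$ch_zbot <- spec$derived$ch_ztop - spec$derived$ch_thickness
  spec
}

#' @noRd
default_frame <- function() {
  f <- diag(3)
  rownames(f) <- c("AP", "ML", "VD")
  f
}

#' @noRd
validate_rudiment_spec <- function(spec) {
  lens <- c(mc_length = spec$mc_length,
            joint_head_radius = spec$joint_head_radius,
            interzone_gap = spec$interzone_gap,
            pq_length = spec$pq_length,
            target_edge_length = spec$target_edge_length,
            neck_radius = spec$neck_radius)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad)) {
    stop("rudiment_spec dimensions must be positive and finite: ",
         paste(bad, collapse = ", "))
  }
  if (spec$interzone_gap >= spec$joint_head_radius) {
    stop("interzone_gap (", spec$interzone_gap,
         ") must be smaller than joint_head_radius (",
         spec$joint_head_radius, ")")
  }
  if (spec$neck_radius >= spec$joint_head_radius) {
    stop("neck_radius must be smaller than joint_head_radius")
  }
  f <- spec$anatomical_frame
  if (!is.matrix(f) || any(dim(f) != c(3, 3)) ||
      max(abs(f %*% t(f) - diag(3))) > 1e-10) {
    stop("anatomical_frame must be a 3x3 orthonormal matrix (to 1e-10)")
  }
  invisible(spec)
}

# Region indicator functions on anatomical coordinates (n x 3 matrix).
# Regions are disjoint by construction so the label is unambiguous.
#' @noRd
region_indicators <- function(spec) {
  d <- spec$derived
  R <- spec$joint_head_radius
  prof <- spec$mc_radius_profile
  g2 <- d$g2
  list(
    MC = function(p) {
      x <- p[, 1]; rho2 <- p[, 2]^2 + p[, 3]^2
      head <- x >= g2 & x <= d$x_neck &
        (x - d$xc)^2 + rho2 <= R^2
      rod <- x > d$x_neck & x <= d$x_tip &
        rho2 <= prof(x - g2)^2
      head | rod
    },
    PQ = function(p) {
      p[, 1] >= d$pq_x0 & p[, 1] <= d$pq_x1 &
        abs(p[, 2]) <= d$pq_half & abs(p[, 3]) <= d$pq_half
    },
    CH = function(p) {
      p[, 1] >= d$ch_x0 & p[, 1] <= d$ch_x1 &
        abs(p[, 2] - spec$ch_anchor_offset[2]) <= d$ch_halfwidth &
        p[, 3] <= d$ch_ztop & p[, 3] >= d$ch_zbot
    },
    interzone = function(p) {
      abs(p[, 1]) <= g2 & p[, 2]^2 + p[, 3]^2 <= d$iz_radius^2
    }
  )
}

#' Closed-form volumes of the generating primitives
#'
#' Exact volumes of the parametric solids from which the rudiment mesh is
#' voxelised; used as the independent oracle for mesh fidelity. The MC rod
#' volume integrates `pi * r(s)^2` by fine quadrature when a custom radius
#' profile is supplied (closed-form frustum otherwise).
#'
#' @param spec A [rudiment_spec()].
#' @return Named numeric vector of region volumes (um^3) plus `total`.
#' @export
analytic_region_volumes <- function(spec) {
  d <- spec$derived
  R <- spec$joint_head_radius
  # spherical zone between planes x = g2 and x = x_neck (sphere frame)
  a <- d$g2 - d$xc
  b <- d$x_neck - d$xc
  zone <- function(t) R^2 * t - t^3 / 3
  v_head <- pi * (zone(b) - zone(a))
  # rod volume by quadrature of the radius profile
  s <- seq(d$x_neck - d$g2, spec$mc_length, length.out = 2001)
  r <- spec$mc_radius_profile(s)
  v_rod <- pi * sum((r[-1]^2 + r[-length(r)]^2) / 2 * diff(s))
  v_mc <- v_head + v_rod
  v_pq <- spec$pq_length * (2 * d$pq_half)^2
  v_ch <- (d$ch_x1 - d$ch_x0) * (2 * d$ch_halfwidth) * d$ch_thickness
  v_iz <- pi * d$iz_radius^2 * spec$interzone_gap
  v <- c(MC = v_mc, PQ = v_pq, CH = v_ch, interzone = v_iz)
  c(v, total = sum(v))
}
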
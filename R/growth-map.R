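#' Cubic ROI grid over a centroid cloud
#'
#' Regions of interest are cubes of side `cube_side` (default 15 um, matching
#' the analysis grid used on the imaging data), anchored at the joint-line
#' landmark, with axes equal to the anatomical frame.
#'
#' @param cells A `centroid_set`, `tracked_pair`, or n x 3 matrix whose
#'   occupied cells define the grid.
#' @param cube_side Cube side (um).
#' @param origin Grid anchor (joint-line centre).
#' @param frame Anatomical frame.
#' @return An `roi_grid` object.
#' @export
roi_grid <- function(cells, cube_side = 15, origin = c(0, 0, 0),
                     frame = default_frame()) {
  stopifnot(cube_side > 0)
  pos <- if (inherits(cells, "tracked_pair")) centroid_positions(cells$t1)
         else if (is.matrix(cells)) cells else centroid_positions(cells)
  idx <- unique(floor(sweep(pos, 2, origin) / cube_side))
  structure(list(origin = origin, cube_side = cube_side,
                 cells = idx, frame = frame),
            class = "roi_grid")
}

#' @noRd
roi_centre <- function(grid, ijk) {
  grid$origin + (ijk + 0.5) * grid$cube_side
}

#' Assemble a growth map over an ROI grid
#'
#' For each occupied ROI, the growth tensor is computed from all conserved
#' link pairs with at least one endpoint (first-timepoint position) inside
#' the ROI — links to neighbours outside the ROI are included. ROIs with too
#' few links or an ill-conditioned texture matrix are flagged invalid and
#' excluded from interpolation support.
#'
#' @param pair A `tracked_pair`.
#' @param grid An [roi_grid()]; defaults to the grid occupied by the pair.
#' @param cutoff Link cutoff, see [build_links()].
#' @param ... Passed to [velocity_gradient_roi()].
#' @return A `growth_map`: list with a per-ROI tibble `rois`, the tensors,
#'   the grid, and the interpolation rule.
#' @export
assemble_growth_map <- function(pair, grid = NULL, cutoff = "auto", ...) {
  stopifnot(inherits(pair, "tracked_pair"))
  if (is.null(grid)) grid <- roi_grid(pair)
  lp <- conserved_link_pairs(pair, cutoff)
  s <- grid$cube_side
  cell_of <- function(p) floor(sweep(p, 2, grid$origin) / s)
  ca <- cell_of(as.matrix(lp[, c("ax", "ay", "az")]))
  cb <- cell_of(as.matrix(lp[, c("bx", "by", "bz")]))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  gk <- key(grid$cells)
  ka <- key(ca); kb <- key(cb)
  tensors <- vector("list", nrow(grid$cells))
  rows <- vector("list", nrow(grid$cells))
  for (r in seq_len(nrow(grid$cells))) {
    sel <- ka == gk[r] | kb == gk[r]
    gt <- velocity_gradient_roi(lp[sel, ], delta_t = pair$delta_t,
                                frame = grid$frame, ...)
    tensors[[r]] <- gt
    ctr <- roi_centre(grid, grid$cells[r, ])
    rows[[r]] <- tibble::tibble(
      roi_i = grid$cells[r, 1], roi_j = grid$cells[r, 2],
      roi_k = grid$cells[r, 3],
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      n_links = gt$n_links, valid = gt$valid,
      rate_VD = if (gt$valid) labelled_rate(gt, "VD") else NA_real_,
      rate_AP = if (gt$valid) labelled_rate(gt, "AP") else NA_real_,
      rate_ML = if (gt$valid) labelled_rate(gt, "ML") else NA_real_)
  }
  rois <- dplyr::bind_rows(rows)
  if (!any(rois$valid)) stop("no valid ROI: growth map cannot be assembled")
  structure(list(rois = rois, tensors = tensors, grid = grid,
                 delta_t = pair$delta_t,
                 interpolation_rule = list(method = "trilinear",
                                           outside = "nearest")),
            class = "growth_map")
}

#' Average growth maps across replicate specimens
#'
#' Component-wise mean of the ROI tensors over maps sharing the same grid
#' origin and cube side; an ROI contributes wherever it is valid.
#'
#' @param maps List of `growth_map`s.
#' @return A `growth_map` on the union of the occupied grids.
#' @export
average_growth_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  g0 <- maps[[1]]$grid
  for (m in maps) {
    if (max(abs(m$grid$origin - g0$origin)) > 1e-9 ||
        abs(m$grid$cube_side - g0$cube_side) > 1e-9) {
      stop("growth maps must share grid origin and cube side to be averaged")
    }
  }
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_cells <- unique(do.call(rbind, lapply(maps, function(m) m$grid$cells)))
  gk <- key(all_cells)
  tensors <- vector("list", nrow(all_cells))
  rows <- vector("list", nrow(all_cells))
  for (r in seq_len(nrow(all_cells))) {
    acc <- matrix(0, 3, 3); cnt <- 0; nl <- 0
    for (m in maps) {
      hit <- which(key(m$grid$cells) == gk[r])
      if (length(hit) && m$tensors[[hit]]$valid) {
        acc <- acc + m$tensors[[hit]]$tensor
        nl <- nl + m$tensors[[hit]]$n_links
        cnt <- cnt + 1
      }
    }
    ctr <- roi_centre(g0, all_cells[r, ])
    if (cnt > 0) {
      gt <- finalize_growth_tensor(acc / cnt, nl, g0$frame)
    } else {
      gt <- structure(list(valid = FALSE, n_links = 0, reason = "no replicate"),
                      class = "growth_tensor")
    }
    tensors[[r]] <- gt
    rows[[r]] <- tibble::tibble(
      roi_i = all_cells[r, 1], roi_j = all_cells[r, 2], roi_k = all_cells[r, 3],
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      n_links = nl, valid = gt$valid,
      rate_VD = if (gt$valid) labelled_rate(gt, "VD") else NA_real_,
      rate_AP = if (gt$valid) labelled_rate(gt, "AP") else NA_real_,
      rate_ML = if (gt$valid) labelled_rate(gt, "ML") else NA_real_)
  }
  grid <- g0; grid$cells <- all_cells
  structure(list(rois = dplyr::bind_rows(rows), tensors = tensors,
                 grid = grid, delta_t = maps[[1]]$delta_t,
                 interpolation_rule = maps[[1]]$interpolation_rule),
            class = "growth_map")
}

#' Interpolate a growth map at arbitrary points
#'
#' Component-wise trilinear interpolation on the ROI lattice (invalid or
#' unoccupied lattice cells are filled with the nearest valid ROI tensor
#' first); queries outside the bounding box of the occupied ROI centres take
#' the nearest valid ROI's tensor. Outputs are exactly symmetric.
#'
#' @param map A `growth_map`.
#' @param points n x 3 matrix (um).
#' @return n x 6 matrix of tensor components in Voigt order
#'   (xx, yy, zz, xy, yz, xz), units 1/s.
#' @export
interpolate_growth <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  valid <- which(map$rois$valid)
  if (!length(valid)) stop("growth map has no valid ROI")
  ctr <- as.matrix(map$rois[valid, c("cx", "cy", "cz")])
  comp <- t(vapply(valid, function(r) voigt6(map$tensors[[r]]$tensor),
                   numeric(6)))

  cells <- as.matrix(map$rois[valid, c("roi_i", "roi_j", "roi_k")])
  rng <- apply(cells, 2, range)
  dims <- rng[2, ] - rng[1, ] + 1L
  lat <- array(NA_real_, c(dims, 6))
  # fill every lattice cell with its own (or the nearest) valid ROI value
  full <- as.matrix(expand.grid(i = rng[1, 1]:rng[2, 1],
                                j = rng[1, 2]:rng[2, 2],
                                k = rng[1, 3]:rng[2, 3]))
  fc <- sweep((full + 0.5) * map$grid$cube_side, 2, -map$grid$origin)
  near <- nearest_row(fc, ctr)
  own <- match(paste(full[, 1], full[, 2], full[, 3]),
               paste(cells[, 1], cells[, 2], cells[, 3]))
  src <- ifelse(is.na(own), near, own)
  for (c6 in 1:6) {
    lat[cbind(full - rep(rng[1, ] - 1L, each = nrow(full)), c6)] <- comp[src, c6]
  }

  s <- map$grid$cube_side
  # continuous lattice coordinates of query points (ROI centres at integers)
  u <- sweep(sweep(points, 2, map$grid$origin), 2, rep(s, 3), "/") - 0.5
  lo <- rng[1, ]; hi <- rng[2, ]
  outside <- u[, 1] < lo[1] | u[, 1] > hi[1] |
             u[, 2] < lo[2] | u[, 2] > hi[2] |
             u[, 3] < lo[3] | u[, 3] > hi[3]
  uc <- pmin(pmax(u[, 1], lo[1]), hi[1])
  vc <- pmin(pmax(u[, 2], lo[2]), hi[2])
  wc <- pmin(pmax(u[, 3], lo[3]), hi[3])
  i0 <- pmin(floor(uc), hi[1] - 1L); if (dims[1] == 1L) i0 <- rep(lo[1], length(uc))
  j0 <- pmin(floor(vc), hi[2] - 1L); if (dims[2] == 1L) j0 <- rep(lo[2], length(vc))
  k0 <- pmin(floor(wc), hi[3] - 1L); if (dims[3] == 1L) k0 <- rep(lo[3], length(wc))
  fu <- if (dims[1] == 1L) rep(0, length(uc)) else uc - i0
  fv <- if (dims[2] == 1L) rep(0, length(vc)) else vc - j0
  fw <- if (dims[3] == 1L) rep(0, length(wc)) else wc - k0
  val <- matrix(0, nrow(points), 6)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fu else 1 - fu) * (if (dj) fv else 1 - fv) *
      (if (dk) fw else 1 - fw)
    ii <- pmin(i0 + di, hi[1]) - (lo[1] - 1L)
    jj <- pmin(j0 + dj, hi[2]) - (lo[2] - 1L)
    kk <- pmin(k0 + dk, hi[3]) - (lo[3] - 1L)
    for (c6 in 1:6) {
      val[, c6] <- val[, c6] + w * lat[cbind(ii, jj, kk, c6)]
    }
  }
  if (any(outside)) {
    near_out <- nearest_row(points[outside, , drop = FALSE], ctr)
    val[outside, ] <- comp[near_out, , drop = FALSE]
  }
  val
}

#' @noRd
nearest_row <- function(q, ref) {
  n <- nrow(q)
  out <- integer(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 2000))) {
    d <- outer(rowSums(q[b, , drop = FALSE]^2), rowSums(ref^2), "+") -
      2 * q[b, , drop = FALSE] %*% t(ref)
    out[b] <- max.col(-d, ties.method = "first")
  }
  out
}

#' @noRd
voigt6 <- function(T) {
  c(T[1, 1], T[2, 2], T[3, 3], T[1, 2], T[2, 3], T[1, 3])
}

#' @noRd
from_voigt6 <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

#' Write / read a growth map as CSV (with a JSON sidecar for grid metadata)
#' @param map A `growth_map`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_growth_map_csv <- function(map, path) {
  tab <- map$rois
  comps <- t(vapply(seq_len(nrow(tab)), function(r) {
    if (map$tensors[[r]]$valid) voigt6(map$tensors[[r]]$tensor) else rep(NA_real_, 6)
  }, numeric(6)))
  colnames(comps) <- c("t_xx", "t_yy", "t_zz", "t_xy", "t_yz", "t_xz")
  utils::write.csv(cbind(as.data.frame(tab), comps), path, row.names = FALSE)
  meta <- list(origin = map$grid$origin, cube_side = map$grid$cube_side,
               delta_t = map$delta_t,
               interpolation_rule = map$interpolation_rule)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_growth_map_csv
#' @export
read_growth_map_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- structure(list(origin = meta$origin, cube_side = meta$cube_side,
                         cells = as.matrix(df[, c("roi_i", "roi_j", "roi_k")]),
                         frame = default_frame()),
                    class = "roi_grid")
  tensors <- lapply(seq_len(nrow(df)), function(r) {
    if (!isTRUE(df$valid[r])) {
      return(structure(list(valid = FALSE, n_links = df$n_links[r],
                            reason = "stored invalid"),
                       class = "growth_tensor"))
    }
    finalize_growth_tensor(from_voigt6(unlist(
      df[r, c("t_xx", "t_yy", "t_zz", "t_xy", "t_yz", "t_xz")])),
      df$n_links[r])
  })
  structure(list(rois = tibble::as_tibble(df[, 1:10]), tensors = tensors,
                 grid = grid, delta_t = meta$delta_t,
                 interpolation_rule = meta$interpolation_rule),
            class = "growth_map")
}
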
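#' Link vectors between neighbouring cell centroids
#'
#' Neighbours are defined by the 3D Delaunay tessellation of the centroid
#' cloud, with an optional length cutoff (default 2.5x the median
#' nearest-neighbour distance) to drop spurious long edges along the convex
#' hull. The tessellation is found by direct empty-circumsphere enumeration
#' over all 4-point subsets, which is exact in general position and entirely
#' adequate for the ~30-cell point sets this statistic is designed for. The
#' neighbour rule is recorded with the result so it can be swapped.
#'
#' @param cells A `centroid_set` (or n x 3 matrix).
#' @param cutoff Length cutoff in um, or `"auto"`.
#' @return Tibble of class `link_set`: columns `i`, `j` (cell ids, i < j),
#'   `lx`, `ly`, `lz`, `len`; attribute `neighbour_rule`.
#' @export
build_links <- function(cells, cutoff = "auto") {
  pos <- if (is.matrix(cells)) cells else centroid_positions(cells)
  ids <- if (is.matrix(cells)) seq_len(nrow(cells)) else cells$cell_id
  n <- nrow(pos)
  if (n < 4) stop("need at least 4 centroids to define neighbours")
  sv <- svd(scale(pos, scale = FALSE))$d
  if (sv[3] < 1e-9 * sv[1]) stop("centroids are (nearly) coplanar; Delaunay neighbours undefined")

  edges <- delaunay_edges(pos)
  l <- pos[edges[, 2], , drop = FALSE] - pos[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(l^2))
  if (identical(cutoff, "auto")) {
    d2 <- as.matrix(stats::dist(pos)); diag(d2) <- Inf
    cutoff <- 2.5 * stats::median(apply(d2, 1, min))
  }
  keep <- len <= cutoff
  out <- tibble::tibble(i = ids[edges[keep, 1]], j = ids[edges[keep, 2]],
                        lx = l[keep, 1], ly = l[keep, 2], lz = l[keep, 3],
                        len = len[keep])
  sw <- out$i > out$j
  if (any(sw)) {
    out[sw, c("i", "j")] <- out[sw, c("j", "i")]
    out[sw, c("lx", "ly", "lz")] <- -out[sw, c("lx", "ly", "lz")]
  }
  class(out) <- c("link_set", class(out))
  attr(out, "neighbour_rule") <- list(method = "delaunay", cutoff = cutoff)
  out
}

# Delaunay edges by brute-force empty-circumsphere testing of all C(n,4)
# tetrahedra (vectorised Cramer solves). O(n^5) but n is ~30 here.
#' @noRd
delaunay_edges <- function(pos) {
  n <- nrow(pos)
  cmb <- utils::combn(n, 4)
  p1 <- pos[cmb[1, ], , drop = FALSE]
  a <- pos[cmb[2, ], , drop = FALSE] - p1
  b <- pos[cmb[3, ], , drop = FALSE] - p1
  cc <- pos[cmb[4, ], , drop = FALSE] - p1
  # solve 2 M x = rhs for circumcentre offset x, M rows a,b,c
  rhs <- cbind(rowSums(a^2), rowSums(b^2), rowSums(cc^2)) / 2
  det3 <- function(u, v, w) {
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  }
  D <- det3(a, b, cc)
  scale2 <- (rowSums(a^2) + rowSums(b^2) + rowSums(cc^2))
  nondeg <- abs(D) > 1e-10 * scale2^1.5
  r1 <- cbind(rhs[, 1], a[, 2], a[, 3]); r2 <- cbind(rhs[, 2], b[, 2], b[, 3]); r3 <- cbind(rhs[, 3], cc[, 2], cc[, 3])
  X <- det3(r1, r2, r3)
  r1 <- cbind(a[, 1], rhs[, 1], a[, 3]); r2 <- cbind(b[, 1], rhs[, 2], b[, 3]); r3 <- cbind(cc[, 1], rhs[, 3], cc[, 3])
  Y <- det3(r1, r2, r3)
  r1 <- cbind(a[, 1], a[, 2], rhs[, 1]); r2 <- cbind(b[, 1], b[, 2], rhs[, 2]); r3 <- cbind(cc[, 1], cc[, 2], rhs[, 3])
  Z <- det3(r1, r2, r3)
  ctr <- cbind(X, Y, Z) / D + p1
  r2ball <- rowSums((ctr - p1)^2)
  empty <- nondeg
  for (q in seq_len(n)) {
    dq <- (ctr[, 1] - pos[q, 1])^2 + (ctr[, 2] - pos[q, 2])^2 +
      (ctr[, 3] - pos[q, 3])^2
    inside <- dq < r2ball * (1 - 1e-9)
    inside[cmb[1, ] == q | cmb[2, ] == q | cmb[3, ] == q | cmb[4, ] == q] <- FALSE
    empty <- empty & !inside
    if (!any(empty)) break
  }
  tets <- cmb[, empty, drop = FALSE]
  if (!ncol(tets)) stop("degenerate point set: no Delaunay tetrahedra found")
  pr <- rbind(tets[c(1, 2), , drop = FALSE], tets[c(1, 3), , drop = FALSE],
              tets[c(1, 4), , drop = FALSE], tets[c(2, 3), , drop = FALSE],
              tets[c(2, 4), , drop = FALSE], tets[c(3, 4), , drop = FALSE])
  e <- cbind(as.vector(pr[seq(1, 12, 2), ]), as.vector(pr[seq(2, 12, 2), ]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Conserved link pairs between two tracked timepoints
#'
#' Links are built from the first timepoint's positions; each link whose cell
#' pair exists at both timepoints is paired with the vector recomputed from
#' the second timepoint's positions.
#'
#' @param pair A `tracked_pair`.
#' @param cutoff Passed to [build_links()].
#' @return Tibble with columns `i`, `j`, `l1x..l1z`, `l2x..l2z`, plus the
#'   midpoint of the first-timepoint link (`mx`, `my`, `mz`) used for ROI
#'   membership; attribute `delta_t`.
#' @export
conserved_link_pairs <- function(pair, cutoff = "auto") {
  stopifnot(inherits(pair, "tracked_pair"))
  links <- build_links(pair$t1, cutoff)
  common <- intersect(pair$t1$cell_id, pair$t2$cell_id)
  keep <- links$i %in% common & links$j %in% common
  links <- links[keep, ]
  if (!nrow(links)) stop("no conserved links between the two timepoints")
  p1 <- centroid_positions(pair$t1); rownames(p1) <- pair$t1$cell_id
  p2 <- centroid_positions(pair$t2); rownames(p2) <- pair$t2$cell_id
  ci <- as.character(links$i); cj <- as.character(links$j)
  l2 <- p2[cj, , drop = FALSE] - p2[ci, , drop = FALSE]
  a1 <- p1[ci, , drop = FALSE]; b1 <- p1[cj, , drop = FALSE]
  out <- tibble::tibble(i = links$i, j = links$j,
                        l1x = links$lx, l1y = links$ly, l1z = links$lz,
                        l2x = l2[, 1], l2y = l2[, 2], l2z = l2[, 3],
                        ax = a1[, 1], ay = a1[, 2], az = a1[, 3],
                        bx = b1[, 1], by = b1[, 2], bz = b1[, 3])
  attr(out, "delta_t") <- pair$delta_t
  attr(out, "neighbour_rule") <- attr(links, "neighbour_rule")
  out
}
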
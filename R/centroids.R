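#' Sample cell centroids inside a mesh region
#'
#' Poisson-disk (dart-throwing) sampling of points uniformly distributed over
#' the region's tetrahedra, respecting a minimum pairwise spacing. About 30
#' chondrocyte centroids populate the modelled portion of the Meckel's
#' cartilage at these stages, which is the default.
#'
#' @param mesh A `labelled_tet_mesh`.
#' @param region Region label (default `"MC"`).
#' @param n Number of centroids.
#' @param min_spacing Minimum pairwise distance (um); 0 gives plain uniform
#'   sampling.
#' @param seed Integer seed.
#' @param timepoint_dpf Age label stored with the set (days post
#'   fertilisation).
#' @return A tibble of class `centroid_set` with columns `cell_id`, `x_um`,
#'   `y_um`, `z_um`, `timepoint_dpf`.
#' @export
sample_cell_centroids <- function(mesh, region = "MC", n = 30,
                                  min_spacing = 4, seed = 1L,
                                  timepoint_dpf = 4) {
  stopifnot(n >= 1, min_spacing >= 0)
  mask <- region_element_mask(mesh, region)
  if (!any(mask)) stop("region has no elements: ", region)
  el <- mesh$elems[mask, , drop = FALSE]
  w <- tet_volumes(mesh$nodes, el)
  set.seed(seed)
  acc <- matrix(NA_real_, n, 3)
  got <- 0L
  max_tries <- max(2000L, 400L * n)
  for (t in seq_len(max_tries)) {
    e <- sample.int(nrow(el), 1, prob = w)
    lam <- -log(stats::runif(4)); lam <- lam / sum(lam)  # uniform barycentric
    p <- colSums(mesh$nodes[el[e, ], ] * lam)
    if (got == 0L ||
        min(colSums((t(acc[seq_len(got), , drop = FALSE]) - p)^2)) >= min_spacing^2) {
      got <- got + 1L
      acc[got, ] <- p
      if (got == n) break
    }
  }
  if (got < n) {
    stop("could not place ", n, " centroids at min_spacing = ", min_spacing,
         " um in region ", region, " (placed ", got, ")")
  }
  out <- tibble::tibble(cell_id = seq_len(n),
                        x_um = acc[, 1], y_um = acc[, 2], z_um = acc[, 3],
                        timepoint_dpf = timepoint_dpf)
  class(out) <- c("centroid_set", class(out))
  attr(out, "region") <- region
  out
}

#' @noRd
centroid_positions <- function(cells) {
  as.matrix(cells[, c("x_um", "y_um", "z_um")])
}

#' @noRd
as_centroid_set <- function(pos, cell_id, timepoint_dpf) {
  out <- tibble::tibble(cell_id = cell_id,
                        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                        timepoint_dpf = timepoint_dpf)
  class(out) <- c("centroid_set", class(out))
  out
}

#' Advect centroids over a window to form a tracked pair
#'
#' The second timepoint is the first advected through the ground-truth flow
#' (sub-stepped integration) plus isotropic Gaussian localisation noise; cell
#' identities are preserved (proliferation over these windows is negligible).
#'
#' @param cells A `centroid_set` at the first timepoint.
#' @param field A `ground_truth_deformation`.
#' @param delta_t Window in seconds (> 0).
#' @param noise_sd Isotropic Gaussian noise s.d. (um) on the second
#'   timepoint; the default 0.3 um is a configuration choice representing
#'   confocal centroid localisation error.
#' @param seed Integer seed for the noise.
#' @return A `tracked_pair`: list with elements `t1`, `t2` (centroid sets
#'   sharing `cell_id`) and `delta_t`.
#' @export
advect_tracked_pair <- function(cells, field, delta_t = 43200,
                                noise_sd = 0.3, seed = 1L) {
  stopifnot(delta_t > 0, noise_sd >= 0)
  p1 <- centroid_positions(cells)
  p2 <- advect_points(p1, field, delta_t)
  if (noise_sd > 0) {
    set.seed(seed)
    p2 <- p2 + matrix(stats::rnorm(length(p2), sd = noise_sd), ncol = 3)
  }
  t2 <- as_centroid_set(p2, cells$cell_id,
                        cells$timepoint_dpf[1] + delta_t / 86400)
  tracked_pair(cells, t2, delta_t)
}

#' Construct a tracked pair from two centroid sets
#' @param t1,t2 `centroid_set` tibbles sharing the same `cell_id`s.
#' @param delta_t Seconds between the timepoints.
#' @return A `tracked_pair`.
#' @export
tracked_pair <- function(t1, t2, delta_t) {
  if (delta_t <= 0) stop("delta_t must be positive")
  if (anyDuplicated(t1$cell_id) || anyDuplicated(t2$cell_id)) {
    stop("cell_ids must be unique within each timepoint")
  }
  if (!setequal(t1$cell_id, t2$cell_id)) {
    stop("tracked pair timepoints must share the same cell_id set")
  }
  t2 <- t2[match(t1$cell_id, t2$cell_id), ]
  structure(list(t1 = t1, t2 = t2, delta_t = delta_t), class = "tracked_pair")
}

#' Write / read centroid tables
#'
#' Plain CSV with columns `cell_id, x_um, y_um, z_um, timepoint_dpf`.
#' @param cells A `centroid_set`.
#' @param path File path.
#' @export
write_centroids_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids_csv
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "x_um", "y_um", "z_um", "timepoint_dpf")
  if (!all(need %in% names(df))) {
    stop("centroid CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- tibble::as_tibble(df[, need])
  class(out) <- c("centroid_set", class(out))
  out
}
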
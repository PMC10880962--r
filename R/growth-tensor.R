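#' Statistical symmetrised velocity gradient of a link ensemble
#'
#' From conserved link pairs \eqn{(l, l')} over a window \eqn{\Delta t}, the
#' texture \eqn{M = \langle l \otimes l \rangle} and link-change
#' \eqn{C = \langle l \otimes (l' - l)/\Delta t \rangle} give the velocity
#' gradient \eqn{V = M^{-1} C}; the returned growth tensor is its symmetric
#' part \eqn{(V + V^T)/2} (units 1/s), a strain-rate-equivalent statistic of
#' how the centroid pattern deforms. Eigen-decomposition is attached and the
#' eigenvectors labelled against the anatomical axes.
#'
#' @param link_pairs Tibble from [conserved_link_pairs()] (or any tibble with
#'   `l1x..l1z`, `l2x..l2z`).
#' @param delta_t Window in seconds; defaults to the tibble's attribute.
#' @param min_links Minimum number of links (default 4).
#' @param max_condition Maximum condition number of the texture matrix before
#'   the ROI is flagged invalid rather than silently inverted.
#' @param frame Anatomical frame for axis labelling.
#' @return A `growth_tensor`: list with `tensor` (3x3 symmetric),
#'   `eigenvalues` (decreasing, 1/s), `eigenvectors` (columns),
#'   `axis_labels`, `angles_deg`, `n_links`, `valid`.
#' @export
velocity_gradient_roi <- function(link_pairs, delta_t = NULL,
                                  min_links = 4, max_condition = 1e6,
                                  frame = default_frame()) {
  if (is.null(delta_t)) delta_t <- attr(link_pairs, "delta_t")
  stopifnot(!is.null(delta_t), delta_t > 0)
  l1 <- as.matrix(link_pairs[, c("l1x", "l1y", "l1z")])
  l2 <- as.matrix(link_pairs[, c("l2x", "l2y", "l2z")])
  n <- nrow(l1)
  invalid <- function(reason) {
    structure(list(tensor = NULL, eigenvalues = NULL, eigenvectors = NULL,
                   axis_labels = NULL, angles_deg = NULL,
                   n_links = n, valid = FALSE, reason = reason),
              class = "growth_tensor")
  }
  if (n < min_links) return(invalid("too few links"))
  M <- crossprod(l1) / n
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 0 || ev[1] / ev[3] > max_condition) {
    return(invalid("ill-conditioned texture matrix"))
  }
  C <- crossprod(l1, (l2 - l1) / delta_t) / n
  V <- solve(M, C)
  T <- (V + t(V)) / 2
  T <- (T + t(T)) / 2  # enforce exact symmetry
  finalize_growth_tensor(T, n, frame)
}

#' @noRd
finalize_growth_tensor <- function(T, n_links, frame = default_frame()) {
  e <- eigen(T, symmetric = TRUE)
  gt <- structure(list(tensor = T, eigenvalues = e$values,
                       eigenvectors = e$vectors, axis_labels = NULL,
                       angles_deg = NULL, n_links = n_links, valid = TRUE),
                  class = "growth_tensor")
  label_axes(gt, frame)
}

#' Label growth-ellipsoid axes by their nearest anatomical axis
#'
#' Each eigenvector is assigned the anatomical axis (VD, AP or ML) from which
#' its angle is smallest, under the constraint that the assignment is a
#' bijection (total angular mismatch minimised over all six permutations).
#' Ties are broken with priority VD > AP > ML so labelling is deterministic.
#'
#' @param t A `growth_tensor` with eigen-decomposition.
#' @param frame 3x3 matrix with rows named among AP/ML/VD.
#' @return The tensor with `axis_labels` (named by VD/AP/ML, value = eigen
#'   index) and `angles_deg` filled in.
#' @export
label_axes <- function(t, frame = default_frame()) {
  stopifnot(inherits(t, "growth_tensor"))
  if (!isTRUE(t$valid)) return(t)
  axes <- frame[c("VD", "AP", "ML"), , drop = FALSE]
  ang <- matrix(0, 3, 3, dimnames = list(c("VD", "AP", "ML"), NULL))
  for (a in 1:3) for (k in 1:3) {
    ang[a, k] <- acos(min(1, abs(sum(axes[a, ] * t$eigenvectors[, k]))))
  }
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tot <- apply(perms, 1, function(p) ang[1, p[1]] + ang[2, p[2]] + ang[3, p[3]])
  ord <- order(tot, ang[1, perms[, 1]], ang[2, perms[, 2]], ang[3, perms[, 3]])
  best <- perms[ord[1], ]
  t$axis_labels <- c(VD = best[1], AP = best[2], ML = best[3])
  t$angles_deg <- c(VD = unname(ang[1, best[1]]), AP = unname(ang[2, best[2]]),
                    ML = unname(ang[3, best[3]])) * 180 / pi
  t
}

#' Growth rate along a labelled anatomical axis
#' @param t A valid `growth_tensor`.
#' @param label One of "VD", "AP", "ML".
#' @return Rate in 1/s.
#' @export
labelled_rate <- function(t, label) {
  stopifnot(isTRUE(t$valid))
  t$eigenvalues[t$axis_labels[[label]]]
}

#' @export
print.growth_tensor <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("<growth_tensor> invalid (", x$reason, "), n_links = ", x$n_links,
        "\n", sep = "")
    return(invisible(x))
  }
  cat("<growth_tensor> n_links =", x$n_links, "\n")
  rates <- vapply(c("VD", "AP", "ML"), function(l) labelled_rate(x, l), 0)
  print(signif(rates, 4))
  invisible(x)
}
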
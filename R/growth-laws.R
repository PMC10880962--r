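#' Baseline growth map evaluated at mesh nodes
#'
#' Interpolates an ROI growth map (the immobilised baseline) to every mesh
#' node, giving the per-node tensor field the mechanobiological growth laws
#' add their stimuli to.
#'
#' @param map A `growth_map` (typically G_imm).
#' @param mesh A `labelled_tet_mesh`.
#' @return A `node_growth_field`: list with `tensors` (N x 6 Voigt), `kind`,
#'   `params`.
#' @export
baseline_node_field <- function(map, mesh) {
  tensors <- interpolate_growth(map, mesh$nodes)
  structure(list(tensors = tensors, kind = "baseline", params = list()),
            class = "node_growth_field")
}

#' @noRd
check_node_field <- function(base, n) {
  if (!inherits(base, "node_growth_field") || nrow(base$tensors) != n) {
    stop("baseline field and mechanical field are not co-registered ",
         "(node counts differ)")
  }
}

#' Average-stress growth law (G_ave)
#'
#' Adds an isotropic mechanobiological increment `-a * S * I3` to the
#' baseline at every node: compression (S < 0) increases all three growth
#' rates, testing the hypothesis that compression levels promote growth.
#'
#' @param baseline A [baseline_node_field()] (G_imm at the nodes).
#' @param S Per-node cycle-averaged hydrostatic stress (kPa).
#' @param a Stress-to-rate modulating variable (1/(kPa s) in the internal
#'   unit system).
#' @return A `node_growth_field` of kind `G_ave`.
#' @export
growth_ave <- function(baseline, S, a) {
  check_node_field(baseline, length(S))
  if (a < 0) stop("modulating variable a must be >= 0")
  out <- baseline
  out$tensors[, 1:3] <- out$tensors[, 1:3] - a * S
  out$kind <- "G_ave"
  out$params <- list(a = a)
  out
}

#' Stress-gradient growth law (G_grad)
#'
#' Adds the axis-wise anisotropic increment
#' `b * |grad sigma_h(peak opening) - grad sigma_h(peak closure)|` to the
#' baseline diagonal: the reversal of the stress gradient over the cycle
#' promotes growth along the axis it reverses in.
#'
#' @param baseline A [baseline_node_field()].
#' @param grad_open,grad_close N x 3 nodal gradients of the hydrostatic
#'   stress at peak opening / peak closure (kPa/um).
#' @param b Gradient-to-rate modulating variable (um/(kPa s)).
#' @return A `node_growth_field` of kind `G_grad`.
#' @export
growth_grad <- function(baseline, grad_open, grad_close, b) {
  if (!all(dim(grad_open) == dim(grad_close))) {
    stop("peak-opening and peak-closure gradients differ in shape")
  }
  check_node_field(baseline, nrow(grad_open))
  if (b < 0) stop("modulating variable b must be >= 0")
  out <- baseline
  out$tensors[, 1:3] <- out$tensors[, 1:3] + b * abs(grad_open - grad_close)
  out$kind <- "G_grad"
  out$params <- list(b = b)
  out
}

#' Compressive stress-gradient growth law (G_comp_grad)
#'
#' Identical to [growth_grad()] except that each peak field is clamped to its
#' compressive part before the gradients are taken: only the variation in
#' compressive stress magnitude acts as the stimulus.
#'
#' @param baseline A [baseline_node_field()].
#' @param sigma_open,sigma_close Per-node hydrostatic stress at the peaks
#'   (kPa).
#' @param b Modulating variable (same value as for G_grad).
#' @param mesh Mesh on which the gradients are evaluated.
#' @return A `node_growth_field` of kind `G_comp_grad`.
#' @export
growth_comp_grad <- function(baseline, sigma_open, sigma_close, b, mesh) {
  go <- nodal_gradient(compressive_clamp(sigma_open), mesh)
  gc <- nodal_gradient(compressive_clamp(sigma_close), mesh)
  out <- growth_grad(baseline, go, gc, b)
  out$kind <- "G_comp_grad"
  out
}

#' Sensitivity calibration of a modulating variable
#'
#' Runs the growth simulation over one 12 h window for each sweep value and
#' picks the value whose simulated MC depth change best matches the
#' physiological target (the depth change produced by the free-to-move
#' growth map), exactly the selection rule used for the published values. If
#' every sweep value undergrows the target, the maximum is returned with a
#' warning.
#'
#' @param which `"a"` or `"b"`.
#' @param sweep Numeric vector of candidate values (>= 2).
#' @param context List with the precomputed pieces: `mesh`, `baseline`
#'   (node field), `S`, `grad_open`, `grad_close`, `sigma_open`,
#'   `sigma_close`, `window`, `mode`, `n_substeps`, `materials`, `bcs`.
#' @param target Target MC depth percent change over the window.
#' @return List with `value`, `sweep_table` (tibble value/length/depth/width
#'   percent change), `achieved`.
#' @export
calibrate_modulating_variable <- function(which = c("a", "b"), sweep, context,
                                          target) {
  which <- match.arg(which)
  stopifnot(length(sweep) >= 2)
  sweep <- sort(sweep)
  base_m <- measure_morphometrics(context$mesh)
  rows <- vector("list", length(sweep))
  for (k in seq_along(sweep)) {
    map <- switch(which,
      a = growth_ave(context$baseline, context$S, sweep[k]),
      b = growth_grad(context$baseline, context$grad_open,
                      context$grad_close, sweep[k]))
    pc <- tryCatch({
      grown <- apply_growth(context$mesh, map, window = context$window,
                            mode = context$mode,
                            n_substeps = context$n_substeps,
                            materials = context$materials, bcs = context$bcs)
      percent_change(base_m, measure_morphometrics(grown))
    }, error = function(e) {
      # extreme sweep values can degenerate the simulation (the analogue of
      # obvious overgrowth); record and exclude from the optimum
      warning("sweep value ", signif(sweep[k], 3), " failed: ",
              conditionMessage(e))
      tibble::tibble(length = NA_real_, depth = NA_real_, width = NA_real_)
    })
    rows[[k]] <- dplyr::mutate(pc, value = sweep[k], .before = 1)
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$depth))) stop("every sweep value failed to simulate")
  err <- abs(tab$depth - target)
  pick <- which.min(err)  # first optimum on ties; NAs never win
  if (pick == which.max(sweep * !is.na(tab$depth)) &&
      all(tab$depth < target, na.rm = TRUE)) {
    warning("target depth change unreachable within the sweep; ",
            "returning the largest feasible sweep value")
  }
  list(value = sweep[pick], sweep_table = tab, achieved = tab$depth[pick],
       target = target, which = which)
}

#' Default log-spaced sweep for a modulating variable
#'
#' The published sensitivity sweeps spanned a 4-fold range for `a` and a
#' 15-fold range for `b`, running from minimal mechanobiological growth at
#' the bottom to obvious joint overgrowth at the top. Those span ratios and
#' endpoint semantics are kept (the printed magnitudes themselves are tied
#' to the original model's unit system and do not transfer): the top of the
#' sweep is the value at which the strong tail of the stimulus (its 99th
#' percentile) would contribute an order-one growth strain over the window
#' -- unambiguous overgrowth -- and the sweep descends by the printed span
#' ratio from there.
#'
#' @param which `"a"` or `"b"`.
#' @param stimulus Per-node stimulus magnitude the variable multiplies
#'   (|S| for `a`, the gradient-difference entries for `b`), over the region
#'   the law acts on.
#' @param window Growth window (s).
#' @param n Number of sweep values.
#' @param overgrowth_strain Growth strain per window defining "obvious
#'   overgrowth" (default 1).
#' @return Numeric vector of length `n`.
#' @export
default_sweep <- function(which = c("a", "b"), stimulus, window = 43200,
                          n = 9, overgrowth_strain = 1) {
  which <- match.arg(which)
  span <- if (which == "a") 4 else 15
  q <- stats::quantile(abs(stimulus), 0.99, names = FALSE)
  if (!is.finite(q) || q == 0) stop("stimulus is identically zero")
  top <- overgrowth_strain / (window * q)
  exp(seq(log(top / span), log(top), length.out = n))
}
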
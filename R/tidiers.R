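#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth map into one row per ROI
#'
#' @param x A `growth_map`.
#' @param ... Unused.
#' @return Tibble with ROI indices, centre coordinates, labelled rates
#'   (1/s), link counts and validity.
#' @method tidy growth_map
#' @export
tidy.growth_map <- function(x, ...) {
  x$rois
}

#' @rdname tidy.growth_map
#' @method glance growth_map
#' @export
glance.growth_map <- function(x, ...) {
  v <- x$rois[x$rois$valid, ]
  tibble::tibble(n_roi = nrow(x$rois), n_valid = nrow(v),
                 median_rate_VD = stats::median(v$rate_VD),
                 median_rate_AP = stats::median(v$rate_AP),
                 median_rate_ML = stats::median(v$rate_ML),
                 delta_t = x$delta_t)
}

#' Tidy a pipeline run into its headline tables
#' @param x A `jawgrowth_run`.
#' @param ... Unused.
#' @return The percent-change table (one row per condition).
#' @method tidy jawgrowth_run
#' @export
tidy.jawgrowth_run <- function(x, ...) {
  x$percent_change
}

#' @rdname tidy.jawgrowth_run
#' @method glance jawgrowth_run
#' @export
glance.jawgrowth_run <- function(x, ...) {
  out <- tibble::tibble(
    seed = x$config$seed,
    opening_um = x$force_calibration$achieved_opening,
    free_length = x$percent_change$length[1],
    free_depth = x$percent_change$depth[1],
    free_width = x$percent_change$width[1],
    imm_length = x$percent_change$length[2],
    imm_depth = x$percent_change$depth[2],
    imm_width = x$percent_change$width[2])
  if (!is.null(x$mechanoregulation)) {
    out$a <- x$mechanoregulation$a
    out$b <- x$mechanoregulation$b
  }
  out
}

#' Plot the labelled growth rates of a growth map
#'
#' One tile per occupied ROI (AP on x, VD on y, faceted by axis label),
#' mirroring how per-axis growth-rate maps are presented.
#'
#' @param object A `growth_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_map
#' @export
autoplot.growth_map <- function(object, ...) {
  d <- tidyr::pivot_longer(object$rois[object$rois$valid, ],
                           cols = dplyr::starts_with("rate_"),
                           names_to = "axis", values_to = "rate",
                           names_prefix = "rate_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cx, y = .data$cz,
                                  fill = .data$rate)) +
    ggplot2::geom_tile(width = object$grid$cube_side,
                       height = object$grid$cube_side) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "AP (um)", y = "VD (um)", fill = "rate (1/s)",
                  title = "Growth map (lateral projection of ROI centres)")
}

#' Plot an extracted outline
#' @param object A tibble from [extract_outline()].
#' @param ... Additional outlines to overlay, named.
#' @return A ggplot.
#' @export
plot_outlines <- function(object, ...) {
  extra <- list(...)
  d <- dplyr::mutate(object, shape = "outline")
  for (nm in names(extra)) {
    d <- dplyr::bind_rows(d, dplyr::mutate(extra[[nm]], shape = nm))
  }
  ax <- attr(object, "axes")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$u, y = .data$v,
                                  colour = .data$shape)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (um)"), y = paste0(ax[2], " (um)"))
}

#' Plot sensitivity-sweep tables
#' @param cal Result of [calibrate_modulating_variable()].
#' @return A ggplot of depth change vs the modulating variable.
#' @export
plot_sweep <- function(cal) {
  ggplot2::ggplot(cal$sweep_table,
                  ggplot2::aes(x = .data$value, y = .data$depth)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cal$target, linetype = 2) +
    ggplot2::geom_vline(xintercept = cal$value, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste("modulating variable", cal$which),
                  y = "MC depth change (%)")
}
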
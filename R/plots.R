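#' Plot PCoA colony scores
#'
#' @param object A `corallux_pcoa` from [trait_pcoa()].
#' @param axes Which two axes to draw.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.corallux_pcoa <- function(object, axes = c(1, 2), ...) {
  ax <- paste0("Axis", axes)
  lab <- sprintf("%s (%.1f%%)", ax, 100 * object$explained[axes])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                               colour = .data$depth_group,
                               shape = .data$depth_group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.68, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "depth group",
                  shape = "depth group") +
    ggplot2::theme_minimal()
}

#' Plot tissue-normalized photosynthetic scores across scenarios
#'
#' One panel per irradiance level; colour encodes the morphotype, shape the
#' P-E parameter set, x the optical scenario / structural variant.
#'
#' @param object A `scenario_results` tibble from [run_scenario_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.scenario_results <- function(object, ...) {
  df <- dplyr::mutate(object, scenario = ifelse(
    .data$structural_variant == "default",
    paste0("optics ", .data$optical_scenario),
    .data$structural_variant))
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$score,
                                   colour = .data$morphotype,
                                   shape = .data$pe_set)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~irradiance, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "photosynthetic score per tissue voxel",
                  colour = "morphotype", shape = "P-E set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a lateral slice of a fluence volume
#'
#' Depth section (x-z) of the relative fluence rate at a fixed y index, with
#' the tissue and skeleton boundaries of the matching label volume overlaid
#' as contours.
#'
#' @param fluence A `fluence_volume`.
#' @param volume The matching [label_volume()] (optional, for boundaries).
#' @param y_index Lateral slice index (default: middle).
#' @return A ggplot.
#' @export
plot_fluence_slice <- function(fluence, volume = NULL, y_index = NULL) {
  d <- dim(fluence$phi)
  if (is.null(y_index)) y_index <- d[2] %/% 2L
  dx <- fluence$resolution
  df <- tidyr::expand_grid(x = seq_len(d[1]), z = seq_len(d[3]))
  df$phi <- fluence$phi[cbind(df$x, y_index, df$z)]
  df$x_mm <- (df$x - 0.5) * dx
  df$z_mm <- (df$z - 0.5) * dx
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm,
                                        fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "relative Φ") +
    ggplot2::labs(x = "x (mm)", y = "depth (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(volume)) {
    df$label <- volume$labels[cbind(df$x, y_index, df$z)]
    p <- p + ggplot2::geom_contour(
      data = df,
      mapping = ggplot2::aes(.data$x_mm, .data$z_mm, z = .data$label),
      breaks = c(0.5, 1.5), colour = "white", linewidth = 0.2,
      inherit.aes = FALSE)
  }
  p
}
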
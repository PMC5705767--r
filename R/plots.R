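#' Maximum-intensity projection plot of an image stack channel
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or role.
#' @param spots Optional spot tibble overlaid as points.
#' @return A ggplot object.
#' @export
plot_projection <- function(stack, channel = "exon", spots = NULL) {
  arr <- get_channel(stack, channel)
  proj <- apply(arr, c(2, 3), max)
  vs <- stack$voxel_size
  df <- tidyr::expand_grid(y = seq_len(nrow(proj)), x = seq_len(ncol(proj)))
  df$intensity <- proj[as.matrix(df[, c("y", "x")])]
  df$y_um <- (df$y - 0.5) * vs[2]
  df$x_um <- (df$x - 0.5) * vs[3]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (μm)", y = "y (μm)",
                  fill = channel,
                  title = sprintf("max projection: %s", channel))
  if (!is.null(spots) && nrow(spots) > 0) {
    p <- p + ggplot2::geom_point(
      data = spots, ggplot2::aes(.data$x_um, .data$y_um),
      colour = "red", shape = 1, size = 1.2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of a per-cell metric by condition
#'
#' @param object A `cell_profiles` tibble.
#' @param metric Column to plot (default: first numeric metric).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_profiles <- function(object, metric = NULL, ...) {
  num <- setdiff(names(object)[vapply(object, is.numeric, TRUE)],
                 c("cell_id", "timepoint"))
  metric <- metric %||% num[1]
  ggplot2::ggplot(object, ggplot2::aes(.data[[metric]])) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::labs(x = metric, y = "cells",
                  title = sprintf("per-cell distribution of %s", metric))
}

#' Per-nucleus boundary residuals before and after warping
#'
#' @param object A `registration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.registration_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$residuals, c("pre_um", "post_um"),
                            names_to = "stage", values_to = "residual_um")
  df$stage <- factor(df$stage, c("pre_um", "post_um"),
                     c("before warp", "after warp"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$nucleus_id),
                                   .data$residual_um, fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "nucleus", y = "mean boundary residual (μm)",
                  fill = NULL, title = "registration residuals per nucleus")
}

#' Scatter plot of a cross-assay correlation
#'
#' @param object An `if_correlation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.if_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data[[object$x_col]],
                               .data[[object$y_col]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(title = sprintf("%s r = %.2f (n = %d)", object$method,
                                  object$r, object$n))
}
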
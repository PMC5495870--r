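#' Plot a time-frequency map
#'
#' @param object A [new_tfm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_tfm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = if (is.na(object$channel)) NULL else object$channel) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap confidence tube
#'
#' @param object A [confidence_tube()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_tube <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a directed network on the schematic scalp layout
#'
#' Edge colour encodes the discretization level; arrows point from source to
#' target.
#'
#' @param object A [discretize()] network.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_network <- function(object, ...) {
  pos <- channel_positions(object$nodes)
  e <- object$edges
  e <- dplyr::left_join(e, pos, by = c(source = "channel"))
  e <- dplyr::rename(e, x0 = "x", y0 = "y")
  e <- dplyr::left_join(e, pos, by = c(target = "channel"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y), size = 8,
                        shape = 21, fill = "white") +
    ggplot2::geom_text(data = pos, ggplot2::aes(.data$x, .data$y,
                                                label = .data$channel), size = 2.6)
  if (nrow(e) > 0) {
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   colour = factor(.data$level), linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")),
      lineend = "round") +
      ggplot2::scale_colour_manual(values = c(`1` = "black", `2` = "forestgreen",
                                              `3` = "red"), name = "level") +
      ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(title = if (!is.null(object$roi)) object$roi$label else NULL)
}

#' Plot PARAFAC loadings by mode and factor
#'
#' @param object A [parafac()] fit.
#' @param ... Unused.
#' @return A ggplot object (factors in columns, modes in rows).
#' @export
autoplot.bn_parafac <- function(object, ...) {
  df <- tidy(object)
  df$mode <- factor(df$mode, levels = c("space", "time", "frequency", "subject"))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$loading)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(mode ~ factor, scales = "free",
                        labeller = ggplot2::labeller(
                          factor = function(x) paste("factor", x))) +
    ggplot2::theme_minimal()
}
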
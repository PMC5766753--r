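#' Plot a quantified tongue
#'
#' Shows the analysed image with detected papilla boundaries, the midline,
#' the 1-cm band edges and the counting circle.
#'
#' @param object An `fp_quant` result.
#' @param image Optional RGB array to use as backdrop; by default the class
#'   map is shown as flat tissue colours.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_quant <- function(object, image = NULL, ...) {
  g <- object$geometry
  H <- nrow(object$class_map); W <- ncol(object$class_map)

  if (is.null(image)) {
    pal <- c("0" = "grey20", "1" = "#c05570", "2" = "#efe0d6", "3" = "#e8a9a9")
    df <- tidyr::expand_grid(y = seq_len(H), x = seq_len(W))
    df$class <- as.character(as.vector(t(unclass(object$class_map))))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_manual(
        values = pal,
        labels = c("0" = "background", "1" = "fungiform",
                   "2" = "filiform", "3" = "base"),
        name = NULL)
  } else {
    df <- tidyr::expand_grid(y = seq_len(H), x = seq_len(W))
    df$col <- grDevices::rgb(t(matrix(aperm(image, c(3L, 2L, 1L)), nrow = 3L)) / 255)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
      ggplot2::scale_fill_identity()
  }

  if ("boundary" %in% names(object$papillae) &&
      nrow(object$papillae) > 0L) {
    bdf <- dplyr::bind_rows(lapply(seq_len(nrow(object$papillae)), function(i) {
      b <- object$papillae$boundary[[i]]
      if (is.null(b)) return(NULL)
      tibble(id = i, x = b[, "x"], y = b[, "y"])
    }))
    if (nrow(bdf) > 0L) {
      p <- p + ggplot2::geom_path(
        data = bdf, ggplot2::aes(group = .data$id),
        colour = "yellow", linewidth = 0.2)
    }
  }

  band_rows <- if (g$tip == "bottom") {
    g$tip_row - g$band_mm / g$mm_per_px
  } else {
    g$tip_row + g$band_mm / g$mm_per_px
  }
  p <- p +
    ggplot2::geom_vline(xintercept = g$midline_col, colour = "blue",
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = band_rows, colour = "blue",
                        linetype = "dotted")
  if (!is.null(g$circle_centre_px)) {
    th <- seq(0, 2 * pi, length.out = 181L)
    r_px <- g$circle_diameter_mm / 2 / g$mm_per_px
    circ <- tibble(x = g$circle_centre_px[1L] + r_px * cos(th),
                   y = g$circle_centre_px[2L] + r_px * sin(th))
    p <- p + ggplot2::geom_path(data = circ, colour = "gold")
  }
  p +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Bar chart of papilla counts per grid
#'
#' @param summary A one-row summary tibble from [fp_summarize()] (or an
#'   `fp_quant` object).
#' @return A ggplot object: counts for L1-L8 and R1-R8, split by side.
#' @export
plot_grid_counts <- function(summary) {
  if (inherits(summary, "fp_quant")) summary <- summary$summary
  grids <- c(paste0("L", 1:8), paste0("R", 1:8))
  df <- tidyr::pivot_longer(summary[grids], dplyr::everything(),
                            names_to = "grid", values_to = "count")
  df$side <- substr(df$grid, 1L, 1L)
  df$number <- factor(substr(df$grid, 2L, 2L), levels = as.character(1:8))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$number, y = .data$count,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(L = "#7da7d9", R = "#d97d7d")) +
    ggplot2::labs(x = "Grid number (1-4 Band 1, 5-8 Band 2)",
                  y = "Papilla count", fill = "Side") +
    ggplot2::theme_minimal()
}
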
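#' Plot a low complexity triangle heatmap
#'
#' Renders the grid as a cartesian heatmap: MMPR (x) increasing left to
#' right, max-residue fraction (y) from 1/wl at the bottom to 1 at the top.
#' Cell fill encodes log10 of the window count — a count of 1 maps to 0 and
#' the scale spans `[0, log10(max count)]` — while empty cells stay
#' background (they are not drawn, avoiding log10(0)). With
#' `show_regions = TRUE` the nested red/green/orange region boundaries are
#' drawn as outlined rectangles at their threshold coordinates.
#'
#' @param object An `lct_grid` (must contain at least one window).
#' @param show_regions Draw the region outlines?
#' @param regions Region tibble; defaults to [lct_regions()].
#' @param title Plot title; defaults to the window count and window length.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @examples
#' g <- triangle_grid(analyze_sequence(polyq_atx1(), wl = 10))
#' ggplot2::autoplot(g, show_regions = FALSE)
autoplot.lct_grid <- function(object, show_regions = TRUE,
                              regions = lct_regions(), title = NULL, ...) {
  if (object$total == 0) abort("cannot plot an empty grid")
  cells <- dplyr::filter(tidy(object), .data$count > 0)
  if (is.null(title)) {
    title <- paste0(object$total, " windows, wl = ", object$wl)
  }
  wl <- object$wl
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                           fill = log10(.data$count))) +
    ggplot2::geom_tile(width = 1, height = 1 / wl) +
    ggplot2::scale_fill_viridis_c(
      name = "log10(windows)",
      limits = c(0, max(log10(max(cells$count)), .Machine$double.eps))
    ) +
    ggplot2::scale_x_continuous(
      breaks = 0:object$x_max,
      limits = c(-0.5, object$x_max + 0.5), expand = c(0, 0)
    ) +
    ggplot2::scale_y_continuous(
      limits = c(1 / wl - 1 / (2 * wl), 1 + 1 / (2 * wl)), expand = c(0, 0)
    ) +
    ggplot2::labs(x = "MMPR (mutations to perfect repeat)",
                  y = "fraction of most frequent amino acid",
                  title = title) +
    ggplot2::theme_minimal()
  if (show_regions) {
    regions$xmax <- object$x_max + 0.5
    regions$ymin <- 1 / wl - 1 / (2 * wl)
    # draw only regions that intersect this grid's canvas (a short x axis,
    # e.g. wl = 10, can sit entirely left of the wl = 20 thresholds)
    regions <- regions[regions$x_gt < regions$xmax &
                         regions$y_lt > regions$ymin, , drop = FALSE]
  }
  if (show_regions && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$x_gt, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$y_lt,
                   colour = .data$name),
      fill = NA, linewidth = 0.6
    ) +
      ggplot2::scale_colour_manual(
        name = "region",
        values = c(red = "red3", green = "green4", orange = "orange2")
      )
  }
  p
}

#' @rdname autoplot.lct_grid
#' @param grid An `lct_grid`.
#' @export
plot_triangle <- function(grid, show_regions = TRUE,
                          regions = lct_regions(), title = NULL) {
  autoplot.lct_grid(grid, show_regions = show_regions, regions = regions,
                    title = title)
}

#' Render a triangle heatmap to an image file
#'
#' @inheritParams plot_triangle
#' @param file Output path.
#' @param format `"png"` or `"svg"`; inferred from the file extension when
#'   omitted.
#' @param width,height Image size in inches.
#' @param dpi Raster resolution (PNG only).
#' @return `file`, invisibly.
#' @export
save_triangle <- function(grid, file, format = NULL, show_regions = TRUE,
                          regions = lct_regions(), title = NULL,
                          width = 6, height = 4.5, dpi = 150) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(file))
  }
  if (!format %in% c("png", "svg")) {
    abort(paste0("unsupported output format '", format,
                 "' (supported: png, svg)"))
  }
  p <- plot_triangle(grid, show_regions = show_regions, regions = regions,
                     title = title)
  device <- if (format == "png") {
    function(filename, ...) grDevices::png(filename, width = width,
                                           height = height, units = "in",
                                           res = dpi)
  } else {
    function(filename, ...) grDevices::svg(filename, width = width,
                                           height = height)
  }
  device(file)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(file)
}
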
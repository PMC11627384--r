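#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory fit
#'
#' Scatter of cells in the 2-D layout, colored by cluster or by final
#' pseudotime, with the inferred lineage drawn as arrows between cluster
#' centroids following the directed cluster edges.
#'
#' @param object A `trajentropy_fit` (run with `layout = TRUE`).
#' @param colour `"cluster"` or `"pseudotime"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajentropy_fit
#' @export
autoplot.trajentropy_fit <- function(object, colour = c("cluster", "pseudotime"),
                                     ...) {
  colour <- match.arg(colour)
  if (is.null(object$layout))
    stop("fit has no layout; rerun infer_trajectory(..., layout = TRUE)",
         call. = FALSE)
  df <- tidy(object)
  centers <- dplyr::summarise(dplyr::group_by(df, .data$cluster),
                              dim1 = mean(.data$dim1),
                              dim2 = mean(.data$dim2), .groups = "drop")
  seg <- dplyr::inner_join(
    dplyr::inner_join(object$cluster_edges, centers,
                      by = c(source = "cluster")),
    centers, by = c(target = "cluster"), suffix = c("", "_end"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
  p <- if (colour == "cluster") {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 1.2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$pseudotime),
                            size = 1.2) +
      ggplot2::scale_colour_viridis_c(name = "pseudotime")
  }
  if (nrow(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$dim1, y = .data$dim2,
                   xend = .data$dim1_end, yend = .data$dim2_end),
      linewidth = 0.7, colour = "grey20",
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")))
  }
  p + ggplot2::geom_point(data = centers, shape = 21, size = 3,
                          fill = "white", colour = "grey20")
}

#' Write trajectory and pseudotime figures to disk
#'
#' Saves `trajectory.<ext>` (cluster coloring + lineage arrows) and
#' `pseudotime.<ext>` (pseudotime coloring) in each requested format.
#'
#' @param fit A `trajentropy_fit` with a layout.
#' @param dir Output directory (created if needed).
#' @param formats Character vector of device extensions (default
#'   `c("svg", "png")`; svg requires cairo and is skipped with a message
#'   when unsupported).
#' @param width,height,dpi Figure geometry passed to [ggplot2::ggsave()].
#' @return Character vector of the files written, invisibly.
#' @export
save_trajectory_plots <- function(fit, dir, formats = c("svg", "png"),
                                  width = 6, height = 5, dpi = 150) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  plots <- list(trajectory = autoplot(fit, "cluster"),
                pseudotime = autoplot(fit, "pseudotime"))
  for (fmt in formats) {
    if (fmt == "svg" && !capabilities("cairo")) {
      message("cairo unavailable; skipping svg output")
      next
    }
    for (nm in names(plots)) {
      path <- file.path(dir, paste0(nm, ".", fmt))
      dev <- if (fmt == "svg") grDevices::svg else NULL
      ggplot2::ggsave(path, plots[[nm]], device = dev %||% fmt,
                      width = width, height = height, dpi = dpi)
      written <- c(written, path)
    }
  }
  invisible(written)
}
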
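#' Single-cell density plot
#'
#' Two-dimensional Gaussian-kernel density plot of a feature pair (default
#' deformability `D3` versus initial diameter `A`), red-to-blue encoding
#' high-to-low density of single-cell measurements. Tables with fewer than
#' 10 rows fall back to a scatter plot with a warning. Gates can be drawn
#' on top with [gate_layer()].
#'
#' @param table Feature table.
#' @param x,y Feature column names.
#' @param bandwidth Optional numeric pair of kernel bandwidths (defaults to
#'   [MASS::bandwidth.nrd()] per axis).
#' @param gridsize Number of grid points per axis.
#' @param file Optional output path; when given the plot is written with
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when written to file.
#' @export
density_plot <- function(table, x = "A", y = "D3", bandwidth = NULL,
                         gridsize = 128L, file = NULL) {
  for (col in c(x, y)) gate_column(table, col)
  xv <- table[[x]]; yv <- table[[y]]
  if (length(xv) < 10L) {
    warnf("fewer than 10 rows; falling back to a scatter plot")
    p <- ggplot2::ggplot(data.frame(x = xv, y = yv),
                         ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(colour = "steelblue") +
      ggplot2::labs(x = x, y = y)
  } else {
    if (is.null(bandwidth))
      bandwidth <- c(MASS::bandwidth.nrd(xv), MASS::bandwidth.nrd(yv))
    kd <- MASS::kde2d(xv, yv, h = bandwidth, n = gridsize)
    grid <- expand.grid(x = kd$x, y = kd$y)
    grid$density <- as.vector(kd$z)
    p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$density)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradientn(
        colours = c("#2166ac", "#67a9cf", "#d1e5f0", "#fddbc7",
                    "#ef8a62", "#b2182b")) +
      ggplot2::labs(x = x, y = y, fill = "density")
    attr(p, "kde") <- kd
  }
  p <- p + ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Gate overlay layer for density plots
#'
#' @param gate A `gate_spec`.
#' @param n_points Resolution of the quantile-ellipse outline.
#' @return A list of ggplot2 layers.
#' @export
gate_layer <- function(gate, n_points = 181L) {
  stopifnot(inherits(gate, "gate_spec"))
  switch(gate$kind,
    size = list(ggplot2::geom_vline(xintercept = gate$a_max,
                                    linetype = "dashed")),
    diagonal = list(
      ggplot2::geom_vline(xintercept = gate$a_max, linetype = "dashed"),
      ggplot2::geom_hline(yintercept = gate$d3_min, linetype = "dashed")),
    quantile = {
      ch <- chol(gate$shape)
      th <- seq(0, 2 * pi, length.out = n_points)
      pts <- t(gate$center + t(cbind(cos(th), sin(th)) %*% ch) * gate$radius)
      df <- data.frame(x = pts[, 1L], y = pts[, 2L])
      list(ggplot2::geom_path(data = df,
                              ggplot2::aes(x = .data$x, y = .data$y),
                              inherit.aes = FALSE, linetype = "dashed"))
    },
    stopf("no overlay for gate kind '%s'", gate$kind))
}
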
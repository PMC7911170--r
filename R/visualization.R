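#' Describe a plot output
#'
#' @param kind One of `"bar3d"`, `"heatmap"`, `"clustermap"`, `"pca_scatter"`.
#' @param output_path Output image path; extension must be `.png`, `.svg`
#'   or `.pdf`.
#' @param title Plot title.
#' @param dpi Raster resolution (png only).
#' @param colormap Optional colormap name understood by
#'   [grDevices::hcl.colors()]; defaults depend on the plotted basis.
#' @param width,height Device size in inches.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(kind = c("heatmap", "bar3d", "clustermap", "pca_scatter"),
                      output_path, title = "", dpi = 150L, colormap = NULL,
                      width = 7, height = 5) {
  kind <- match.arg(kind)
  ext <- tolower(sub(".*\\.", "", output_path))
  if (!ext %in% c("png", "svg", "pdf")) {
    abort_motif(sprintf("output extension must be png, svg or pdf (got .%s)", ext))
  }
  structure(list(kind = kind, output_path = output_path, title = title,
                 dpi = dpi, colormap = colormap, width = width,
                 height = height, ext = ext),
            class = "plot_spec")
}

open_device <- function(spec) {
  switch(spec$ext,
         png = grDevices::png(spec$output_path, width = spec$width,
                              height = spec$height, units = "in",
                              res = spec$dpi),
         pdf = grDevices::pdf(spec$output_path, width = spec$width,
                              height = spec$height),
         svg = grDevices::svg(spec$output_path, width = spec$width,
                              height = spec$height))
}

matrix_long <- function(v) {
  data.frame(
    sequence = factor(rep(rownames(v), times = ncol(v)),
                      levels = rev(rownames(v))),
    motif = factor(rep(colnames(v), each = nrow(v)), levels = colnames(v)),
    value = as.vector(v))
}

#' 3D bar chart of a feature matrix
#'
#' Grouped three-axis bars (motifs across, sequences in depth, value as bar
#' height) drawn with an oblique cabinet projection; rear sequences are
#' drawn first so nearer bars occlude them. Intended for small motif
#' subsets, e.g. the frequencies of a handful of dinucleotides over the
#' first few sequences.
#'
#' @param matrix A `feature_matrix`.
#' @param spec A [plot_spec()] (`kind = "bar3d"`).
#' @param override Allow more than 50 rows / 64 columns (illegible but
#'   permitted).
#' @return The output path, invisibly.
#' @export
plot_bar3d <- function(matrix, spec, override = FALSE) {
  v <- as_values(matrix)
  if (!override && (nrow(v) > 50L || ncol(v) > 64L)) {
    abort_motif(paste0("matrix too large for a legible bar chart (",
                       nrow(v), "x", ncol(v),
                       "); subset motifs/sequences or set override = TRUE"))
  }
  n <- nrow(v); m <- ncol(v)
  zmax <- max(v, 1e-12)
  cols <- grDevices::hcl.colors(max(n, 2L), spec$colormap %||% "Dark 3")
  # cabinet projection: unit depth step shifts (dx, dy) on the page
  dx <- 0.45; dy <- 0.35; bw <- 0.6
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 6), xpd = NA)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, m + 1 + n * dx),
                        ylim = c(-0.05, 1.15 + n * dy * 0.35))
  sc <- 1 / zmax * 0.9
  for (i in rev(seq_len(n))) {        # back rows first
    ox <- (i - 1) * dx; oy <- (i - 1) * dy * 0.35
    for (j in seq_len(m)) {
      h <- v[i, j] * sc
      x0 <- j - bw / 2 + ox; x1 <- j + bw / 2 + ox
      y0 <- oy; y1 <- oy + h
      col <- cols[i]
      graphics::polygon(c(x0, x1, x1, x0), c(y0, y0, y1, y1),
                        col = col, border = "grey20")
      graphics::polygon(c(x0, x1, x1 + dx * 0.5, x0 + dx * 0.5),
                        c(y1, y1, y1 + dy * 0.2, y1 + dy * 0.2),
                        col = grDevices::adjustcolor(col, 0.8),
                        border = "grey20")
      graphics::polygon(c(x1, x1 + dx * 0.5, x1 + dx * 0.5, x1),
                        c(y0, y0 + dy * 0.2, y1 + dy * 0.2, y1),
                        col = grDevices::adjustcolor(col, 0.6),
                        border = "grey20")
    }
  }
  graphics::axis(1, at = seq_len(m), labels = colnames(v), las = 2)
  graphics::axis(2, at = seq(0, 0.9, length.out = 5),
                 labels = signif(seq(0, zmax, length.out = 5), 3), las = 1)
  graphics::legend("topright", legend = rownames(v), fill = cols[seq_len(n)],
                   title = "sequence", bty = "n", cex = 0.8)
  graphics::title(main = spec$title, xlab = "motif",
                  ylab = if (inherits(matrix, "feature_matrix"))
                    matrix$basis else "value")
  invisible(spec$output_path)
}

basis_fill <- function(basis, colormap = NULL) {
  if (identical(basis, "dratio")) {
    # diverging, centered at D = 1 so over/under-representation is symmetric
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 1,
                                  name = "D-ratio")
  } else {
    ggplot2::scale_fill_viridis_c(option = colormap %||% "viridis",
                                  name = "value")
  }
}

#' Heatmap of a feature matrix
#'
#' One colored tile per sequence x motif cell. Frequencies use a
#' perceptually uniform sequential map; D-ratios use a diverging map
#' centered at D = 1.
#'
#' @param matrix A `feature_matrix` with finite values.
#' @param spec A [plot_spec()].
#' @return Invisibly, a list with `path` and the ggplot object `plot`.
#' @export
plot_heatmap <- function(matrix, spec) {
  v <- as_values(matrix)
  if (nrow(v) == 0L || ncol(v) == 0L) abort_motif("empty matrix")
  df <- matrix_long(v)
  basis <- if (inherits(matrix, "feature_matrix")) matrix$basis else "value"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$sequence,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    basis_fill(basis, spec$colormap) +
    ggplot2::labs(title = spec$title, x = "motif", y = "sequence") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  open_device(spec)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(list(path = spec$output_path, plot = p))
}

#' Clustered heatmap from a precomputed clustermap ordering
#'
#' Renders the matrix with rows and columns permuted by the
#' [clustermap()] result and draws the corresponding dendrograms
#' (via pheatmap, fed this package's own hclust trees).
#'
#' @param result A `clustermap_result` computed from `matrix`.
#' @param matrix The same `feature_matrix` the ordering was computed from.
#' @param spec A [plot_spec()].
#' @return The output path, invisibly.
#' @export
plot_clustermap <- function(result, matrix, spec) {
  if (!inherits(result, "clustermap_result")) {
    abort_motif("'result' must come from clustermap()")
  }
  v <- as_values(matrix)
  if (!identical(result$dim, dim(v))) {
    abort_motif(sprintf("ordering was computed for a %dx%d matrix, got %dx%d",
                        result$dim[1], result$dim[2], nrow(v), ncol(v)))
  }
  pal <- if (inherits(matrix, "feature_matrix") && matrix$basis == "dratio") {
    grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  } else {
    grDevices::hcl.colors(101, spec$colormap %||% "Viridis")
  }
  ph <- pheatmap::pheatmap(v, cluster_rows = result$row_hclust,
                           cluster_cols = result$col_hclust,
                           color = pal, main = spec$title, silent = TRUE)
  open_device(spec)
  on.exit(grDevices::dev.off())
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  invisible(spec$output_path)
}

#' PCA scatter plot of a clustering result
#'
#' Plots the 2-D principal-component embedding stored on a [pca_kmeans()]
#' result, one color and legend entry per cluster.
#'
#' @param result A `clustering_result` with an `embedding` (i.e. produced
#'   by [pca_kmeans()]).
#' @param spec A [plot_spec()].
#' @return Invisibly, a list with `path` and the ggplot object `plot`.
#' @export
plot_pca_scatter <- function(result, spec) {
  if (!inherits(result, "clustering_result") || is.null(result$embedding)) {
    abort_motif("result has no embedding; run pca_kmeans() to produce one")
  }
  df <- data.frame(pc1 = result$embedding[, 1L],
                   pc2 = if (ncol(result$embedding) > 1L)
                     result$embedding[, 2L] else 0,
                   cluster = factor(result$labels))
  ev <- result$explained_variance
  lab <- function(i) {
    if (!is.null(ev) && length(ev) >= i)
      sprintf("PC%d (%.1f%% variance)", i, 100 * ev[i]) else sprintf("PC%d", i)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                        color = .data$cluster)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::labs(title = spec$title, x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal(base_size = 10)
  open_device(spec)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(list(path = spec$output_path, plot = p))
}
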
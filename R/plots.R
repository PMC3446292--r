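# cumulative-bp layout for one genome's top-k scaffolds (decreasing length)
dotplot_axis <- function(annot, top_k) {
  scaf <- scaffold_table(annot) %>%
    arrange(dplyr::desc(.data$length)) %>%
    head(top_k) %>%
    mutate(offset = cumsum(dplyr::lag(.data$length, default = 0)))
  scaf
}

#' Lay out an ortholog dot plot
#'
#' Computes the drawing geometry of a scaffold-vs-scaffold ortholog dot
#' plot: scaffolds of each genome in decreasing size order on cumulative bp
#' axes, one dot per ortholog pair at the two gene midpoints, dots classed by
#' strand agreement, and one box per scaffold pair optionally shaded by its
#' synteny Z-score (classes: `undefined`, `z <= 3`, `z > 3`).
#'
#' @inheritParams build_contingency
#' @param zmatrix Optional `scaffold_pair_z` tibble from
#'   [scaffold_pair_significance()].
#' @param top_k Number of largest scaffolds of each genome to draw
#'   (default 29).
#' @return List with tibbles `dots`, `boxes`, `axis_a`, `axis_b`.
#' @export
dotplot_spec <- function(map, annot_a, annot_b, zmatrix = NULL, top_k = 29) {
  map <- validate_map(map, annot_a, annot_b)
  ax_a <- dotplot_axis(annot_a, top_k)
  ax_b <- dotplot_axis(annot_b, top_k)
  ga <- gene_table(annot_a) %>% mutate(mid = (.data$start + .data$end) / 2)
  gb <- gene_table(annot_b) %>% mutate(mid = (.data$start + .data$end) / 2)
  dots <- map %>%
    inner_join(
      ga %>% select(gene_a = "gene_id", scaffold_a = "scaffold_id",
                    mid_a = "mid", strand_a = "strand"),
      by = "gene_a"
    ) %>%
    inner_join(
      gb %>% select(gene_b = "gene_id", scaffold_b = "scaffold_id",
                    mid_b = "mid", strand_b = "strand"),
      by = "gene_b"
    ) %>%
    inner_join(ax_a %>% select(scaffold_a = "scaffold_id", offset_a = "offset"),
      by = "scaffold_a"
    ) %>%
    inner_join(ax_b %>% select(scaffold_b = "scaffold_id", offset_b = "offset"),
      by = "scaffold_b"
    ) %>%
    mutate(
      x = .data$offset_a + .data$mid_a,
      y = .data$offset_b + .data$mid_b,
      strand_class = ifelse(.data$strand_a == .data$strand_b,
        "same strand", "opposite strand"
      )
    ) %>%
    select("gene_a", "gene_b", "scaffold_a", "scaffold_b", "x", "y", "strand_class")
  boxes <- tidyr::expand_grid(
    scaffold_a = ax_a$scaffold_id, scaffold_b = ax_b$scaffold_id
  ) %>%
    inner_join(ax_a %>% select(scaffold_a = "scaffold_id",
                               xmin = "offset", len_a = "length"),
      by = "scaffold_a"
    ) %>%
    inner_join(ax_b %>% select(scaffold_b = "scaffold_id",
                               ymin = "offset", len_b = "length"),
      by = "scaffold_b"
    ) %>%
    mutate(xmax = .data$xmin + .data$len_a, ymax = .data$ymin + .data$len_b)
  if (!is.null(zmatrix)) {
    boxes <- boxes %>%
      left_join(
        as_tibble(zmatrix) %>% select("scaffold_a", "scaffold_b", "z", "undefined"),
        by = c("scaffold_a", "scaffold_b")
      ) %>%
      mutate(z_class = dplyr::case_when(
        is.na(.data$undefined) | .data$undefined ~ "undefined",
        .data$z > 3 ~ "z > 3",
        TRUE ~ "z <= 3"
      ))
  } else {
    boxes$z_class <- "undefined"
  }
  list(dots = dots, boxes = boxes, axis_a = ax_a, axis_b = ax_b)
}

#' Draw an ortholog dot plot
#'
#' Orthologous genes as dots at gene-midpoint coordinates, red for
#' same-strand and green for opposite-strand pairs; scaffold-pair boxes
#' shaded by Z-score class, with significantly syntenic pairs (z > 3)
#' in orange.
#'
#' @inheritParams dotplot_spec
#' @param point_size Dot size.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(map, annot_a, annot_b, zmatrix = NULL, top_k = 29,
                         point_size = 0.6) {
  spec <- dotplot_spec(map, annot_a, annot_b, zmatrix, top_k)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = spec$boxes,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$z_class
      ),
      colour = "grey60", linewidth = 0.2
    ) +
    ggplot2::geom_point(
      data = spec$dots,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$strand_class),
      size = point_size
    ) +
    ggplot2::scale_fill_manual(
      values = c("z > 3" = "#fdae61", "z <= 3" = "white", "undefined" = "grey92"),
      name = "synteny"
    ) +
    ggplot2::scale_colour_manual(
      values = c("same strand" = "red3", "opposite strand" = "green4"),
      name = "orientation"
    ) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.1f Mb", x / 1e6)) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f Mb", x / 1e6)) +
    ggplot2::labs(x = annot_a$species, y = annot_b$species) +
    ggplot2::theme_minimal()
}

#' Render a dot plot to SVG or PNG
#'
#' @inheritParams plot_dotplot
#' @param out_path Output file path.
#' @param format `"png"` or `"svg"`.
#' @param width,height Figure size in inches.
#' @return `out_path`, invisibly.
#' @export
render_dotplot <- function(map, annot_a, annot_b, zmatrix = NULL, top_k = 29,
                           out_path, format = c("png", "svg"),
                           width = 7, height = 7) {
  format <- match.arg(format)
  p <- plot_dotplot(map, annot_a, annot_b, zmatrix, top_k)
  dev <- if (format == "png") grDevices::png else grDevices::svg
  if (format == "png") {
    grDevices::png(out_path, width = width, height = height,
                   units = "in", res = 150)
  } else {
    grDevices::svg(out_path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out_path)
}

#' Plot a windowed GC track
#'
#' One line per scaffold; planted or biological high-GC repeat clusters
#' appear as local peaks.
#'
#' @param track A `gc_track` from [gc_windows()].
#' @return A ggplot object.
#' @export
plot_gc_track <- function(track) {
  ggplot2::ggplot(
    track,
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$gc_fraction)
  ) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~scaffold_id, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "GC fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gc_track <- function(object, ...) plot_gc_track(object)

#' @export
autoplot.scaffold_pair_z <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$scaffold_a, y = .data$scaffold_b, fill = .data$z)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", high = "#fdae61", na.value = "grey92") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
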
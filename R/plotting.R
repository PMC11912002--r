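# Panel rendering and figure assembly.
#
# Panels are ggplot objects carrying a `locus_window` attribute
# (chrom/start/end); assemble_figure() refuses to stack panels whose windows
# differ, and pins every panel to exactly the same x-limits with
# coord_cartesian(expand = FALSE) — the alignment guarantee the whole package
# is built around.

#' Default LD bin colours
#'
#' Classic LocusZoom-style scheme: red for the strongest bin descending to
#' navy, grey for missing LD, purple for the index variant.
#'
#' @return Named character vector of colours, one per [ld_category()] level.
#' @export
ld_colors <- function() {
  c("none" = "grey60",
    "0.0-0.2" = "#191970",   # navy
    "0.2-0.4" = "#87CEEB",   # sky blue
    "0.4-0.6" = "#32CD32",   # green
    "0.6-0.8" = "#FFA500",   # orange
    "0.8-1.0" = "#FF0000",   # red
    "index" = "#7D26CD")     # purple
}

theme_locus <- function(base_size = 11) {
  ggplot2::theme_classic(base_size = base_size) +
    ggplot2::theme(
      panel.grid = ggplot2::element_blank(),
      strip.background = ggplot2::element_blank(),
      legend.key.size = ggplot2::unit(0.9, "lines")
    )
}

set_panel_window <- function(p, locus, kind) {
  attr(p, "locus_window") <- list(chrom = locus$chrom, start = locus$start,
                                  end = locus$end)
  attr(p, "locus") <- locus
  attr(p, "panel_kind") <- kind
  p
}

#' Panel window metadata
#'
#' @param p A panel produced by [plot_scatter()], [plot_eqtl()] or
#'   [plot_genetrack()].
#' @return List with `chrom`, `start`, `end`, or `NULL` for foreign plots.
#' @export
panel_window <- function(p) attr(p, "locus_window", exact = TRUE)

# shared shape logic: typed -> filled circle vs imputed open-ish square;
# direction -> up/down triangles; shapes 21-25 so LD fill applies.
variant_shapes <- function(dat, shape_by) {
  if (shape_by == "auto") {
    shape_by <- if ("typed" %in% names(dat) &&
                    any(!is.na(dat$typed) & !dat$typed)) "typed" else "none"
  }
  switch(
    shape_by,
    typed = ifelse(is.na(dat$typed) | dat$typed, 21, 22),
    direction = ifelse(is.na(dat$direction) | dat$direction == 0, 21,
                       ifelse(dat$direction > 0, 24, 25)),
    rep(21, nrow(dat))
  )
}

#' Render the association scatter panel of a locus
#'
#' Points at `(pos, -log10 p)`, coloured by LD bin when LD is attached
#' (see [ld_category()]), with the index variant drawn last (topmost) as a
#' purple diamond. Symbols can encode the typed-vs-imputed flag (circle vs
#' square) or effect direction (up/down triangles). When a recombination
#' track is attached it is drawn as a step line against a right-hand
#' secondary axis in cM/Mb (fixed 0-100 scale by default).
#'
#' @param locus A [locus()] object.
#' @param shape_by `"none"`, `"typed"`, `"direction"`, or `"auto"`
#'   (typed if informative).
#' @param colors Named colour vector for LD bins; default [ld_colors()].
#' @param point_size Point size.
#' @param default_color Fill used when no LD is attached.
#' @param show_recomb Draw the recombination overlay if attached.
#' @param recomb_limits Right-axis limits in cM/Mb (default `c(0, 100)`).
#' @param labels Variant ids to label (see [label_points()]); `TRUE` labels
#'   the index variant.
#' @param title Optional panel title.
#' @param cap Passed to [neglog10()].
#' @return A ggplot panel carrying locus-window metadata for
#'   [assemble_figure()].
#' @export
plot_scatter <- function(locus, shape_by = c("auto", "none", "typed",
                                             "direction"),
                         colors = ld_colors(), point_size = 2.1,
                         default_color = "grey30", show_recomb = TRUE,
                         recomb_limits = c(0, 100), labels = NULL,
                         title = NULL, cap = 300) {
  shape_by <- match.arg(shape_by)
  stopifnot(inherits(locus, "locus"))
  if (!nrow(locus$data)) {
    warn("empty locus: rendering an empty scatter panel.")
    p <- ggplot2::ggplot() +
      ggplot2::scale_x_continuous(
        labels = function(x) format(x / 1e6, trim = TRUE)) +
      ggplot2::coord_cartesian(xlim = c(locus$start, locus$end),
                               ylim = c(0, 1), expand = FALSE) +
      ggplot2::labs(x = sprintf("Chromosome %s (Mb)", locus$chrom),
                    y = expression(-log[10](italic(p)))) +
      theme_locus()
    return(set_panel_window(p, locus, "scatter"))
  }

  dat <- tidy(locus, cap = cap)
  has_ld <- "ld_cat" %in% names(dat)
  dat$.shape <- variant_shapes(dat, shape_by)
  ymax <- max(dat$logp, 1) * 1.08

  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$logp))

  if (show_recomb && !is.null(locus$recomb) && nrow(locus$recomb)) {
    rec <- recomb_step_data(locus)
    scale <- ymax / (recomb_limits[2] - recomb_limits[1])
    p <- p + ggplot2::geom_step(
      data = rec,
      ggplot2::aes(x = .data$pos,
                   y = (.data$rate - recomb_limits[1]) * scale),
      colour = "#6BAED6", linewidth = 0.45, inherit.aes = FALSE) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(
          ~ . / scale + recomb_limits[1],
          name = "Recombination rate (cM/Mb)"))
  }

  main <- dat[!dat$is_index, , drop = FALSE]
  idx <- dat[dat$is_index, , drop = FALSE]
  if (has_ld) {
    p <- p +
      ggplot2::geom_point(
        data = main,
        ggplot2::aes(fill = .data$ld_cat), shape = main$.shape,
        size = point_size, colour = "grey25", stroke = 0.3) +
      ggplot2::scale_fill_manual(values = colors, drop = FALSE,
                                 name = expression(italic(r)^2),
                                 breaks = rev(LD_LEVELS))
  } else {
    p <- p + ggplot2::geom_point(
      data = main, shape = main$.shape, fill = default_color,
      size = point_size, colour = "grey25", stroke = 0.3)
  }
  if (nrow(idx)) {
    p <- p + ggplot2::geom_point(
      data = idx, shape = 23, size = point_size * 1.5,
      fill = unname(colors["index"]), colour = "black", stroke = 0.4)
  }

  p <- p +
    ggplot2::scale_x_continuous(
      labels = function(x) format(x / 1e6, trim = TRUE)) +
    ggplot2::coord_cartesian(xlim = c(locus$start, locus$end),
                             ylim = c(0, ymax), expand = FALSE) +
    ggplot2::labs(x = sprintf("Chromosome %s (Mb)", locus$chrom),
                  y = expression(-log[10](italic(p))), title = title) +
    theme_locus()
  p <- set_panel_window(p, locus, "scatter")
  if (!is.null(labels)) {
    ids <- if (isTRUE(labels)) NULL else labels
    p <- label_points(p, ids = ids)
  }
  p
}

# step-line data for the clipped recombination segments: one point per
# segment start plus a closing point at the window end.
recomb_step_data <- function(locus) {
  tr <- locus$recomb
  tibble(pos = c(tr$start, tr$end[nrow(tr)]),
         rate = c(tr$rate, tr$rate[nrow(tr)]))
}

#' Render an eQTL panel for a locus
#'
#' Scatter of eQTL `-log10(p)` by position with up/down triangles for the
#' direction of the expression effect (circle when unknown), aligned to the
#' locus window so it can be stacked with the GWAS panel.
#'
#' @param locus A [locus()] with an attached eQTL table
#'   (see [attach_overlays()]).
#' @param gene,tissue Optional filters when the table covers several.
#' @param color Point fill colour.
#' @param point_size Point size.
#' @return A ggplot panel carrying locus-window metadata.
#' @export
plot_eqtl <- function(locus, gene = NULL, tissue = NULL,
                      color = "#2C7FB8", point_size = 2.1) {
  stopifnot(inherits(locus, "locus"))
  if (is.null(locus$eqtl)) {
    abort("locus has no eQTL table; use attach_overlays() first.",
          class = "locusviz_config_error")
  }
  eq <- locus$eqtl
  if (!is.null(gene)) eq <- eq[eq$gene %in% gene, , drop = FALSE]
  if (!is.null(tissue)) eq <- eq[eq$tissue %in% tissue, , drop = FALSE]
  eq$logp <- neglog10(eq$p)
  eq$.shape <- ifelse(is.na(eq$direction) | eq$direction == 0, 21,
                      ifelse(eq$direction > 0, 24, 25))
  ymax <- max(eq$logp, 1) * 1.08
  lab <- unique(stats::na.omit(eq$gene))
  p <- ggplot2::ggplot(eq, ggplot2::aes(x = .data$pos, y = .data$logp)) +
    ggplot2::geom_point(shape = eq$.shape, fill = color, colour = "grey25",
                        size = point_size, stroke = 0.3) +
    ggplot2::scale_x_continuous(
      labels = function(x) format(x / 1e6, trim = TRUE)) +
    ggplot2::coord_cartesian(xlim = c(locus$start, locus$end),
                             ylim = c(0, ymax), expand = FALSE) +
    ggplot2::labs(
      x = sprintf("Chromosome %s (Mb)", locus$chrom),
      y = expression(-log[10](italic(p)) ~ eQTL),
      title = if (length(lab) == 1) paste0("eQTL: ", lab) else NULL) +
    theme_locus()
  set_panel_window(p, locus, "eqtl")
}

#' Render the gene track panel
#'
#' Draws each gene as an intron line across its (window-clipped) span with
#' exon rectangles, strand arrowheads (omitted when strand is unknown), and
#' its symbol at the side computed by [layout_gene_track()]. Genes on the
#' highlight list are drawn in `highlight_color`; genes clipped by a row cap
#' are summarised in a "+N more" caption. Spans truncated by the window get
#' no terminal arrowhead on the cut side.
#'
#' @param locus A [locus()] object (its genes are laid out internally), or a
#'   ready-made `track_layout`.
#' @param window Required when a `track_layout` is given without a locus.
#' @param highlight Character vector of gene symbols to highlight.
#' @param gene_color,highlight_color Track colours.
#' @param max_rows Optional row cap (see [layout_gene_track()]).
#' @param text_size Label text size (mm as in ggplot2).
#' @param filter_biotype Optional biotypes to keep, e.g. `"protein_coding"`.
#' @return A ggplot panel carrying locus-window metadata; the layout used is
#'   stored in attribute `"layout"`.
#' @export
plot_genetrack <- function(locus, window = NULL, highlight = character(),
                           gene_color = "#4477AA", highlight_color = "red",
                           max_rows = NULL, text_size = 2.9,
                           filter_biotype = NULL) {
  if (inherits(locus, "track_layout")) {
    layout <- locus
    window <- attr(layout, "window") %||% window
    loc <- structure(list(chrom = unique(layout$chrom)[1] %||% "?",
                          start = window[1], end = window[2],
                          data = tibble(), index = NULL, genes = layout,
                          ld = NULL, recomb = NULL, eqtl = NULL),
                     class = "locus")
  } else {
    stopifnot(inherits(locus, "locus"))
    loc <- locus
    genes <- loc$genes
    if (!is.null(filter_biotype)) {
      genes <- genes[!is.na(genes$biotype) &
                       genes$biotype %in% filter_biotype, , drop = FALSE]
    }
    layout <- layout_gene_track(genes, c(loc$start, loc$end),
                                max_rows = max_rows)
  }
  wstart <- loc$start; wend <- loc$end
  n_rows <- max(attr(layout, "n_rows"), 1L)
  clipped <- attr(layout, "clipped")

  p <- ggplot2::ggplot()
  if (nrow(layout)) {
    layout$y <- -layout$row
    layout$color <- ifelse(layout$symbol %in% highlight, highlight_color,
                           gene_color)
    # intron line across the clipped span
    p <- p + ggplot2::geom_segment(
      data = layout,
      ggplot2::aes(x = .data$disp_start, xend = .data$disp_end,
                   y = .data$y, yend = .data$y),
      colour = layout$color, linewidth = 0.5)
    # exon rectangles (clipped to the window)
    ex <- tidyr::unnest(
      layout[, c("gene_id", "y", "color", "exons")], "exons")
    ex <- ex[ex$start <= wend & ex$end >= wstart, , drop = FALSE]
    if (nrow(ex)) {
      ex$start <- pmax(ex$start, wstart)
      ex$end <- pmin(ex$end, wend)
      p <- p + ggplot2::geom_rect(
        data = ex,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = .data$y - 0.3, ymax = .data$y + 0.3),
        fill = ex$color, colour = NA)
    }
    # strand arrowheads at the 3' end of the drawn span
    arr <- layout[!is.na(layout$strand), , drop = FALSE]
    if (nrow(arr)) {
      alen <- 0.012 * (wend - wstart + 1)
      fwd <- arr$strand == "+"
      cut3 <- ifelse(fwd, arr$truncated_right, arr$truncated_left)
      arr <- arr[!cut3, , drop = FALSE]
      fwd <- fwd[!cut3]
      if (nrow(arr)) {
        arr$x0 <- ifelse(fwd, arr$disp_end, arr$disp_start)
        arr$x1 <- ifelse(fwd, pmin(arr$disp_end + alen, wend),
                         pmax(arr$disp_start - alen, wstart))
        p <- p + ggplot2::geom_segment(
          data = arr,
          ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y,
                       yend = .data$y),
          colour = arr$color, linewidth = 0.4,
          arrow = grid::arrow(length = grid::unit(0.12, "cm"),
                              type = "open"))
      }
    }
    # symbol labels at the computed side
    pad <- 0.004 * (wend - wstart + 1)
    layout$label_x <- ifelse(layout$label_side == "left",
                             layout$disp_start - pad,
                             layout$disp_end + pad)
    layout$hjust <- ifelse(layout$label_side == "left", 1, 0)
    p <- p + ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$label_x, y = .data$y, label = .data$symbol),
      hjust = layout$hjust, size = text_size, fontface = "italic",
      colour = layout$color)
  }
  if (!is.null(clipped) && nrow(clipped)) {
    p <- p + ggplot2::labs(caption = sprintf("+%d more gene(s) not shown",
                                             nrow(clipped)))
  }
  p <- p +
    ggplot2::scale_x_continuous(
      labels = function(x) format(x / 1e6, trim = TRUE)) +
    ggplot2::coord_cartesian(xlim = c(wstart, wend),
                             ylim = c(-(n_rows + 0.8), -0.2),
                             expand = FALSE) +
    ggplot2::labs(x = sprintf("Chromosome %s (Mb)", loc$chrom)) +
    theme_locus() +
    ggplot2::theme(axis.line.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_blank())
  p <- set_panel_window(p, loc, "genetrack")
  attr(p, "layout") <- layout
  p
}

#' Greedy non-overlapping label placement
#'
#' Pure layout routine used by [label_points()]: labels are processed from
#' the highest point down; each label box starts just above its point and is
#' nudged upward until it overlaps no previously placed box. Guaranteed
#' disjoint boxes; exported so the geometry can be tested directly.
#'
#' @param x,y Point coordinates (data units).
#' @param labels Label text.
#' @param box_w,box_h Label box sizes in data units (vectors recycled).
#' @param y_offset Initial gap between point and box centre.
#' @return Tibble with `x`, `y` (point), `lx`, `ly` (box centre), `label`,
#'   `box_w`, `box_h`.
#' @export
place_labels <- function(x, y, labels, box_w, box_h,
                         y_offset = box_h) {
  n <- length(x)
  box_w <- rep_len(box_w, n)
  box_h <- rep_len(box_h, n)
  y_offset <- rep_len(y_offset, n)
  ord <- order(-y, x)
  lx <- x
  ly <- rep(NA_real_, n)
  placed <- matrix(numeric(0), ncol = 4)  # x0, x1, y0, y1
  for (i in ord) {
    cy <- y[i] + y_offset[i] + box_h[i] / 2
    repeat {
      x0 <- lx[i] - box_w[i] / 2; x1 <- lx[i] + box_w[i] / 2
      y0 <- cy - box_h[i] / 2; y1 <- cy + box_h[i] / 2
      clash <- nrow(placed) > 0 &&
        any(placed[, 1] < x1 & placed[, 2] > x0 &
              placed[, 3] < y1 & placed[, 4] > y0)
      if (!clash) break
      cy <- cy + box_h[i] * 1.15
    }
    ly[i] <- cy
    placed <- rbind(placed, c(lx[i] - box_w[i] / 2, lx[i] + box_w[i] / 2,
                              cy - box_h[i] / 2, cy + box_h[i] / 2))
  }
  tibble(x = x, y = y, lx = lx, ly = ly, label = labels,
         box_w = box_w, box_h = box_h)
}

#' Label scatter points with text and leader lines
#'
#' Adds variant-id labels to a scatter or eQTL panel, with greedy vertical
#' nudging so no two label boxes overlap, and a leader line from the label
#' box edge down to the point. With `ids = NULL` the index variant is
#' labelled. Unknown ids produce a warning and are skipped.
#'
#' @param panel A panel from [plot_scatter()] or [plot_eqtl()].
#' @param ids Character vector of variant ids; `NULL` labels the index
#'   variant.
#' @param text_size Label text size.
#' @return The panel with label layers added.
#' @export
label_points <- function(panel, ids = NULL, text_size = 2.9) {
  locus <- attr(panel, "locus", exact = TRUE)
  if (is.null(locus)) {
    abort("label_points() needs a panel created by this package.",
          class = "locusviz_config_error")
  }
  dat <- tidy(locus)
  if (is.null(ids)) {
    if (is.null(locus$index) || !"id" %in% names(locus$index)) {
      warn("no index variant to label.")
      return(panel)
    }
    ids <- locus$index$id
  }
  known <- ids %in% dat$id
  if (any(!known)) {
    warn(sprintf("label_points: skipping unknown id(s): %s",
                 paste(ids[!known], collapse = ", ")))
    ids <- ids[known]
  }
  if (!length(ids)) return(panel)
  pts <- dat[match(ids, dat$id), , drop = FALSE]
  xr <- locus$end - locus$start + 1
  yr <- max(dat$logp, 1) * 1.08
  lab <- place_labels(pts$pos, pts$logp, pts$id,
                      box_w = (nchar(pts$id) + 1) * 0.011 * xr,
                      box_h = 0.055 * yr,
                      y_offset = 0.035 * yr)
  panel +
    ggplot2::geom_segment(
      data = lab,
      ggplot2::aes(x = .data$lx, xend = .data$x,
                   y = .data$ly - .data$box_h / 2, yend = .data$y),
      colour = "grey40", linewidth = 0.3, inherit.aes = FALSE) +
    ggplot2::geom_label(
      data = lab,
      ggplot2::aes(x = .data$lx, y = .data$ly, label = .data$label),
      size = text_size, label.padding = grid::unit(0.12, "lines"),
      label.size = 0.15, inherit.aes = FALSE)
}

#' Stack panels into one aligned multi-panel locus figure
#'
#' Panels are stacked top-to-bottom with a single shared x-axis; every panel
#' must cover exactly the same chromosome window, otherwise an alignment
#' error is raised (the package never silently rescales). X-limits are
#' bit-identical across panels by construction. The gene track, when
#' present, goes to the bottom by convention (pass panels in the order you
#' want; this function does not reorder).
#'
#' @param ... Panels (or a single list of panels), top to bottom.
#' @param heights Relative panel heights; default 3 per scatter/eQTL panel
#'   and 1.6 per gene track.
#' @param title Optional figure title.
#' @return A patchwork figure carrying the shared window as an attribute.
#' @export
assemble_figure <- function(..., heights = NULL, title = NULL) {
  panels <- list(...)
  if (length(panels) == 1 && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "ggplot")) {
    panels <- panels[[1]]
  }
  if (!length(panels)) {
    abort("assemble_figure() needs at least one panel.",
          class = "locusviz_config_error")
  }
  windows <- lapply(panels, panel_window)
  if (any(vapply(windows, is.null, logical(1)))) {
    abort("every panel must carry locus-window metadata.",
          class = "locusviz_alignment_error")
  }
  ref <- windows[[1]]
  same <- vapply(windows, function(w) {
    identical(w$chrom, ref$chrom) && identical(w$start, ref$start) &&
      identical(w$end, ref$end)
  }, logical(1))
  if (!all(same)) {
    bad <- which(!same)[1]
    abort(sprintf(
      "alignment error: panel %d spans %s:%s-%s but panel 1 spans %s:%s-%s; refusing to rescale.",
      bad, windows[[bad]]$chrom, windows[[bad]]$start, windows[[bad]]$end,
      ref$chrom, ref$start, ref$end),
      class = "locusviz_alignment_error")
  }

  kinds <- vapply(panels, function(p) attr(p, "panel_kind") %||% "scatter",
                  character(1))
  heights <- heights %||% ifelse(kinds == "genetrack", 1.6, 3)
  n <- length(panels)
  # single shared x-axis: strip axis furniture from all but the bottom panel
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      panels[[i]] <- panels[[i]] +
        ggplot2::theme(axis.title.x = ggplot2::element_blank(),
                       axis.text.x = ggplot2::element_blank(),
                       axis.ticks.x = ggplot2::element_blank())
    }
  }
  fig <- patchwork::wrap_plots(panels, ncol = 1, heights = heights)
  if (!is.null(title)) {
    fig <- fig + patchwork::plot_annotation(title = title)
  }
  attr(fig, "locus_window") <- ref
  attr(fig, "panels") <- panels
  attr(fig, "locus") <- attr(panels[[1]], "locus", exact = TRUE)
  fig
}

#' One-call standard locus figure
#'
#' Convenience wrapper building the canonical stack: GWAS scatter (with
#' recombination overlay if attached), optional eQTL panel, gene track at
#' the bottom.
#'
#' @param locus A [locus()] object (overlays already attached as desired).
#' @param eqtl Include an eQTL panel if the locus has an eQTL table.
#' @param highlight Gene symbols to highlight in the track.
#' @param labels Variant ids to label, or `TRUE` for the index variant.
#' @param title Figure title.
#' @param max_rows Gene-track row cap.
#' @param ... Passed to [plot_scatter()].
#' @return A patchwork figure.
#' @export
plot_locus <- function(locus, eqtl = TRUE, highlight = character(),
                       labels = NULL, title = NULL, max_rows = NULL, ...) {
  panels <- list(plot_scatter(locus, labels = labels, ...))
  if (eqtl && !is.null(locus$eqtl) && nrow(locus$eqtl)) {
    panels <- c(panels, list(plot_eqtl(locus)))
  }
  if (nrow(locus$genes)) {
    panels <- c(panels, list(plot_genetrack(locus, highlight = highlight,
                                            max_rows = max_rows)))
  }
  assemble_figure(panels, title = title)
}

#' @rdname plot_locus
#' @param object A [locus()] object.
#' @method autoplot locus
#' @export
autoplot.locus <- function(object, ...) plot_locus(object, ...)

#' Manhattan-style overview of a peak scan
#'
#' @param object A `gwas_peaks` table (with the scanned `stats` attached via
#'   the `stats` argument for the background points).
#' @param stats Optional `sumstats` to draw as background.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gwas_peaks
#' @export
autoplot.gwas_peaks <- function(object, stats = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(stats)) {
    bg <- as_tibble(stats)
    bg$logp <- neglog10(bg$p)
    bg$.x <- genome_x(bg$chrom, bg$pos)
    p <- p + ggplot2::geom_point(
      data = bg, ggplot2::aes(x = .data$.x, y = .data$logp),
      colour = "grey70", size = 0.4)
  }
  pk <- as_tibble(object)
  pk$logp <- neglog10(pk$p)
  pk$.x <- genome_x(pk$chrom, pk$pos)
  p +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(x = .data$.x, y = .data$logp),
                        colour = "#7D26CD", shape = 18, size = 2.4) +
    ggplot2::geom_hline(yintercept = neglog10(attr(object, "p_cutoff")),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Genome position", y = expression(-log[10](italic(p)))) +
    theme_locus()
}

genome_x <- function(chrom, pos) {
  r <- chrom_rank(chrom)
  r * 1e9 + pos
}

#' Arrange several locus figures on one page
#'
#' Places figures in row-major order on a `rows x cols` grid; each figure
#' keeps its own x-axis (different loci are expected). Empty cells are left
#' blank; supplying more figures than cells is an error.
#'
#' @param figures List of figures from [assemble_figure()]/[plot_locus()].
#' @param nrow,ncol Grid dimensions.
#' @return A patchwork figure.
#' @export
multi_locus_page <- function(figures, nrow, ncol) {
  if (length(figures) > nrow * ncol) {
    abort(sprintf("%d figures do not fit a %dx%d grid.",
                  length(figures), nrow, ncol),
          class = "locusviz_config_error")
  }
  cells <- lapply(figures, patchwork::wrap_elements)
  n_blank <- nrow * ncol - length(cells)
  if (n_blank > 0) {
    cells <- c(cells, replicate(n_blank, patchwork::plot_spacer(),
                                simplify = FALSE))
  }
  patchwork::wrap_plots(cells, nrow = nrow, ncol = ncol, byrow = TRUE)
}
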
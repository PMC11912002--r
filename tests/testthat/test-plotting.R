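# Plotting: panel contents, coordinate alignment, label collision, gene
# track geometry, export formats.

panel_xrange <- function(p) {
  ggplot2::ggplot_build(p)$layout$panel_params[[1]]$x.range
}

test_that("every locus variant appears exactly once in the scatter panel", {
  loc <- demo_locus()
  p <- plot_scatter(loc)
  b <- ggplot2::ggplot_build(p)
  pts <- dplyr::bind_rows(
    lapply(b$data, function(d) if (all(c("x", "y") %in% names(d)) &&
                                   "shape" %in% names(d)) d))
  expect_equal(nrow(pts), nrow(loc$data))
  expect_setequal(pts$x, loc$data$pos)
})

test_that("without LD all non-index points share the default colour", {
  loc <- locus(tiny_stats(), chrom = "7", start = 1, end = 1000)
  b <- ggplot2::ggplot_build(plot_scatter(loc, default_color = "grey30"))
  layers <- Filter(function(d) "fill" %in% names(d) && nrow(d) > 0, b$data)
  main <- layers[[1]]
  expect_equal(nrow(main), 2)  # 3 variants, one is the index
  expect_equal(unique(main$fill), "grey30")
})

test_that("point colours follow the LD category of every variant", {
  loc <- demo_locus()
  td <- tidy(loc)
  b <- ggplot2::ggplot_build(plot_scatter(loc))
  pal <- ld_colors()
  layers <- Filter(function(d) "fill" %in% names(d) && nrow(d) > 1, b$data)
  main <- layers[[1]]
  want <- td[!td$is_index, ]
  # build data is ordered as supplied; check per-point fill against the map
  expect_equal(main$fill[order(main$x)],
               unname(pal[as.character(want$ld_cat[order(want$pos)])]))
})

test_that("the index variant is drawn topmost with the distinct symbol", {
  loc <- demo_locus()
  b <- ggplot2::ggplot_build(plot_scatter(loc))
  last_pts <- b$data[[length(b$data)]]
  expect_equal(nrow(last_pts), 1)
  expect_equal(last_pts$shape, 23)
  expect_equal(last_pts$x, loc$index$pos)
})

test_that("a recomb overlay adds the secondary axis in cM/Mb", {
  loc <- demo_locus()
  p <- plot_scatter(loc)
  pp <- ggplot2::ggplot_build(p)$layout$panel_params[[1]]
  expect_true("y.sec" %in% names(pp))
  expect_match(p$scales$get_scales("y")$secondary.axis$name, "cM/Mb")
})

test_that("typed/imputed and direction symbol mappings are honoured", {
  loc <- demo_locus(with_overlays = FALSE)
  b <- ggplot2::ggplot_build(plot_scatter(loc, shape_by = "typed"))
  pts <- b$data[[1]]
  td <- tidy(loc)[!tidy(loc)$is_index, ]
  expect_setequal(unique(pts$shape), c(21, 22))
  expect_equal(pts$shape[order(pts$x)],
               ifelse(td$typed[order(td$pos)], 21, 22))
  b2 <- ggplot2::ggplot_build(plot_scatter(loc, shape_by = "direction"))
  expect_true(all(b2$data[[1]]$shape %in% c(21, 24, 25)))
})

test_that("empty loci render an empty panel with a warning", {
  suppressWarnings(loc <- locus(tiny_stats(), chrom = "7", start = 500,
                                end = 600))
  expect_warning(p <- plot_scatter(loc), "empty")
  expect_equal(panel_window(p)$start, 500)
})

test_that("gene track rows reproduce the layout row assignments", {
  loc <- demo_locus()
  p <- plot_genetrack(loc)
  lay <- attr(p, "layout")
  b <- ggplot2::ggplot_build(p)
  segs <- b$data[[1]]  # intron lines, one per placed gene
  expect_equal(nrow(segs), nrow(lay))
  expect_equal(sort(unique(segs$y)), sort(unique(-lay$row)))
  # each gene's intron line sits exactly on its layout row band
  expect_equal(segs$y[order(segs$x)], -lay$row[order(lay$disp_start)])
})

test_that("one gene with two exons draws two rectangles and one line", {
  ann <- load_gene_models(fixture_gff3(withr::local_tempfile(fileext = ".gff3")))
  ss <- as_sumstats(data.frame(chrom = "7", pos = 2000, p = 0.1))
  loc <- locus(ss, chrom = "7", start = 1, end = 6000, annotation = ann)
  b <- ggplot2::ggplot_build(plot_genetrack(loc))
  segs <- b$data[[1]]
  rects <- b$data[[2]]
  expect_equal(nrow(segs), 1)
  expect_equal(nrow(rects), 2)
})

test_that("highlighted genes change colour and the caption counts clipped genes", {
  loc <- demo_locus()
  p <- plot_genetrack(loc, highlight = "GENE1")
  b <- ggplot2::ggplot_build(p)
  lay <- attr(p, "layout")
  segs <- b$data[[1]]
  hl <- segs$colour[order(segs$x)][order(lay$disp_start) %in%
                                    which(lay$symbol == "GENE1")]
  cols <- unique(segs$colour)
  expect_true("red" %in% segs$colour[lay$symbol[order(lay$disp_start)] == "GENE1"])
  p2 <- plot_genetrack(loc, max_rows = 1)
  if (nrow(attr(attr(p2, "layout"), "clipped"))) {
    expect_match(p2$labels$caption, "more gene")
  }
})

test_that("strand-unknown genes are drawn without arrowheads", {
  genes <- random_gene_set(2, seed = 44)
  genes$strand <- c("+", NA)
  lay <- layout_gene_track(genes, c(1, 1.3e6))
  p <- plot_genetrack(lay)
  b <- ggplot2::ggplot_build(p)
  arrow_layer <- Filter(function(d) nrow(d) > 0 &&
                          all(c("xend", "yend") %in% names(d)), b$data)
  # the arrow layer (second segment layer) holds only the stranded gene
  expect_equal(nrow(arrow_layer[[2]]), 1)
})

test_that("assembled panels share bit-identical x-limits", {
  loc <- demo_locus()
  fig <- plot_locus(loc)
  panels <- attr(fig, "panels")
  expect_gte(length(panels), 3)  # scatter + eqtl + genetrack
  ranges <- lapply(panels, panel_xrange)
  for (r in ranges[-1]) expect_identical(r, ranges[[1]])
})

test_that("panels from different windows are refused, not rescaled", {
  ss <- random_stats(200, seed = 3)
  loc1 <- locus(ss, chrom = "1", start = 1, end = 2e6)
  loc2 <- locus(ss, chrom = "1", start = 1, end = 3e6)
  expect_error(assemble_figure(plot_scatter(loc1), plot_scatter(loc2)),
               class = "locusviz_alignment_error")
  foreign <- ggplot2::ggplot()
  expect_error(assemble_figure(plot_scatter(loc1), foreign),
               class = "locusviz_alignment_error")
})

test_that("single-panel figures assemble and autoplot works", {
  loc <- demo_locus(with_overlays = FALSE)
  fig <- assemble_figure(plot_scatter(loc))
  expect_identical(attr(fig, "locus_window")$chrom, "1")
  expect_s3_class(autoplot(loc), "patchwork")
})

test_that("place_labels always yields pairwise-disjoint boxes", {
  for (seed in 1:10) {
    n <- 8
    pts <- withr::with_seed(seed, {
      list(x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 10))
    })
    lab <- place_labels(pts$x, pts$y, sprintf("rs%d", 1:n),
                        box_w = 18, box_h = 0.8)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        x_overlap <- abs(lab$lx[i] - lab$lx[j]) <
          (lab$box_w[i] + lab$box_w[j]) / 2
        y_overlap <- abs(lab$ly[i] - lab$ly[j]) <
          (lab$box_h[i] + lab$box_h[j]) / 2
        expect_false(x_overlap && y_overlap,
                     info = sprintf("seed %d pair %d-%d", seed, i, j))
      }
    }
  }
})

test_that("two nearly coincident points get displaced, anchored labels", {
  lab <- place_labels(c(50, 50.5), c(5, 5.01), c("rs_a", "rs_b"),
                      box_w = 20, box_h = 1)
  expect_false(abs(lab$ly[1] - lab$ly[2]) < 1)  # boxes disjoint vertically
  expect_equal(lab$x, c(50, 50.5))              # anchors untouched
})

test_that("label_points labels the index by default and warns on unknown ids", {
  loc <- demo_locus()
  p <- plot_scatter(loc)
  p_lab <- label_points(p)
  expect_gt(length(p_lab$layers), length(p$layers))
  expect_warning(label_points(p, ids = c(loc$index$id, "rs_nope")),
                 "rs_nope")
})

test_that("multi-locus pages keep per-figure x-ranges and reject overflow", {
  ss <- random_stats(500, seed = 6)
  figs <- lapply(list(c(1e5, 9e5), c(2e6, 2.8e6), c(3e6, 4e6)), function(w) {
    suppressWarnings(plot_locus(locus(ss, chrom = "1", start = w[1],
                                      end = w[2])))
  })
  page <- multi_locus_page(figs, nrow = 2, ncol = 2)
  expect_s3_class(page, "patchwork")
  expect_error(multi_locus_page(figs, nrow = 1, ncol = 2),
               class = "locusviz_config_error")
  # x-ranges of the source panels unchanged by page assembly
  r_before <- panel_xrange(attr(figs[[1]], "panels")[[1]])
  page  # building the page must not mutate the figures
  expect_identical(panel_xrange(attr(figs[[1]], "panels")[[1]]), r_before)
})
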
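# Figure export: single figures to PDF/SVG/PNG, batches streamed one figure
# per page to a multi-page PDF, and a self-contained interactive HTML export
# with one hover tooltip per variant.

#' Export a figure (or a batch of figures) to file
#'
#' Format is taken from the file extension unless given. PDF export accepts
#' a list of figures and writes one per page, streaming them one at a time
#' so 100+ locus batches stay within bounded memory. SVG and PNG accept a
#' single figure. HTML produces a self-contained hover-enabled document (see
#' [export_html()]) and requires a figure built by this package (it uses the
#' embedded locus data).
#'
#' @param figure A figure (ggplot/patchwork), or for PDF a list of figures.
#' @param path Output path; the directory must exist and be writable.
#' @param format `"auto"`, `"pdf"`, `"svg"`, `"png"` or `"html"`.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG.
#' @return `path`, invisibly.
#' @export
export_figure <- function(figure, path, format = c("auto", "pdf", "svg",
                                                   "png", "html"),
                          width = 8, height = 7, dpi = 300) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("pdf", "svg", "png", "html")) {
      abort(sprintf("cannot infer export format from '%s'.", path),
            class = "locusviz_config_error")
    }
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    abort(sprintf("output directory not writable: %s", dir),
          class = "locusviz_io_error")
  }
  figures <- if (is.list(figure) && !inherits(figure, "ggplot") &&
                 !inherits(figure, "patchwork")) figure else list(figure)

  switch(
    format,
    pdf = {
      grDevices::pdf(path, width = width, height = height, onefile = TRUE,
                     useDingbats = FALSE)
      on.exit(grDevices::dev.off(), add = TRUE)
      for (f in figures) print(f)
    },
    svg = {
      grDevices::svg(path, width = width, height = height)
      on.exit(grDevices::dev.off(), add = TRUE)
      print(figures[[1]])
    },
    png = {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = dpi)
      on.exit(grDevices::dev.off(), add = TRUE)
      print(figures[[1]])
    },
    html = export_html(figures[[1]], path, width = width * 100,
                       height = height * 72)
  )
  invisible(path)
}

#' Export a locus scatter as a self-contained interactive HTML document
#'
#' Writes a single-file HTML page with an inline SVG of the association
#' scatter; every variant is one SVG point carrying a native hover tooltip
#' (`<title>`) with its id, position and p-value, so points can be
#' identified by hovering in any browser with no external dependencies.
#'
#' @param figure A figure or panel built from a locus (its embedded locus
#'   data is used), or a [locus()] object directly.
#' @param path Output path.
#' @param width,height Pixel dimensions of the drawing.
#' @return `path`, invisibly.
#' @export
export_html <- function(figure, path, width = 900, height = 520) {
  locus <- if (inherits(figure, "locus")) figure
  else attr(figure, "locus", exact = TRUE)
  if (is.null(locus)) {
    abort("HTML export needs a figure built from a locus object.",
          class = "locusviz_config_error")
  }
  dat <- tidy(locus)
  pal <- ld_colors()
  fill <- if ("ld_cat" %in% names(dat)) unname(pal[as.character(dat$ld_cat)])
  else rep("#4D4D4D", nrow(dat))
  fill[dat$is_index] <- unname(pal["index"])

  m <- c(left = 60, right = 20, top = 20, bottom = 45)
  xr <- c(locus$start, locus$end)
  ymax <- max(dat$logp, 1) * 1.08
  sx <- function(x) m["left"] + (x - xr[1]) / (xr[2] - xr[1]) *
    (width - m["left"] - m["right"])
  sy <- function(y) height - m["bottom"] - y / ymax *
    (height - m["top"] - m["bottom"])

  circles <- sprintf(
    paste0('<circle cx="%.2f" cy="%.2f" r="%s" fill="%s" stroke="#333" ',
           'stroke-width="0.4"><title>%s</title></circle>'),
    sx(dat$pos), sy(dat$logp), ifelse(dat$is_index, "5", "3.5"), fill,
    sprintf("%s | %s:%s | p=%.3g",
            if ("id" %in% names(dat)) dat$id else ".",
            dat$chrom, format(dat$pos, scientific = FALSE, trim = TRUE),
            dat$p))

  yt <- pretty(c(0, ymax), n = 5)
  yt <- yt[yt >= 0 & yt <= ymax]
  xt <- pretty(xr, n = 6)
  xt <- xt[xt >= xr[1] & xt <= xr[2]]
  axes <- c(
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
            sx(xr[1]), sy(0), sx(xr[2]), sy(0)),
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
            sx(xr[1]), sy(0), sx(xr[1]), sy(ymax)),
    sprintf(paste0('<text x="%.1f" y="%.1f" font-size="11" ',
                   'text-anchor="middle">%.2f</text>'),
            sx(xt), sy(0) + 16, xt / 1e6),
    sprintf(paste0('<text x="%.1f" y="%.1f" font-size="11" ',
                   'text-anchor="end">%g</text>'),
            sx(xr[1]) - 6, sy(yt) + 4, yt),
    sprintf(paste0('<text x="%.1f" y="%.1f" font-size="12" ',
                   'text-anchor="middle">Chromosome %s (Mb)</text>'),
            (sx(xr[1]) + sx(xr[2])) / 2, height - 8, locus$chrom),
    sprintf(paste0('<text x="14" y="%.1f" font-size="12" ',
                   'text-anchor="middle" transform="rotate(-90 14 %.1f)">',
                   '-log10(p)</text>'),
            (sy(0) + sy(ymax)) / 2, (sy(0) + sy(ymax)) / 2))

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>locus %s:%s-%s</title></head><body>", locus$chrom,
            format(locus$start, scientific = FALSE),
            format(locus$end, scientific = FALSE)),
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            as.integer(width), as.integer(height)),
    axes, circles, "</svg>", "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Count pages of a PDF written by [export_figure()]
#'
#' Utility for batch-export bookkeeping (each exported locus is one page).
#'
#' @param path PDF path.
#' @return Integer page count.
#' @export
pdf_page_count <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw[raw > as.raw(0L) & raw <= as.raw(127L)])
  m <- gregexpr("/Type\\s*/Page[^s]", txt)[[1]]
  if (m[1] == -1) 0L else length(m)
}
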
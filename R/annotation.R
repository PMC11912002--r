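# Gene annotation: load gene models from GFF3/GTF, query them by region,
# and pack them into non-overlapping display rows for the gene track.

empty_gene_annotation <- function() {
  structure(
    tibble(gene_id = character(), symbol = character(), chrom = character(),
           start = numeric(), end = numeric(), strand = character(),
           biotype = character(), exons = list()),
    class = c("gene_annotation", "tbl_df", "tbl", "data.frame")
  )
}

first_non_null <- function(df, candidates) {
  for (nm in candidates) if (nm %in% names(df)) return(df[[nm]])
  rep(NA_character_, nrow(df))
}

# rtracklayer parses Parent as a CharacterList; flatten to the first parent.
flatten_parent <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(as.list(x), function(p) if (length(p)) as.character(p[1]) else
    NA_character_, character(1))
}

#' Load gene models from a GFF3 or GTF file
#'
#' Parses the file (via `rtracklayer`), assembles one model per gene with the
#' union of all exons across its transcripts, and returns an indexed,
#' region-queryable annotation table. Transcript-level detail is deliberately
#' collapsed: the gene track draws one row per gene.
#'
#' @param path Path to a GFF3 or GTF file (uncompressed or gzipped).
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return A `gene_annotation` tibble with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`, `strand`, `biotype` and a list-column `exons`
#'   of `(start, end)` tibbles (merged, non-overlapping, sorted).
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' ann <- simulate_genes("1", c(1, 1e6), n_genes = 3, seed = 1, path = gff)
#' load_gene_models(gff)
#' @export
load_gene_models <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path),
          class = "locusviz_io_error")
  }
  if (format == "auto") {
    ext <- tolower(sub("\\.gz$", "", basename(path)))
    format <- if (grepl("\\.gtf$", ext)) "gtf" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3"),
    error = function(e) {
      abort(sprintf("failed to parse %s as %s: %s", path, format,
                    conditionMessage(e)),
            class = "locusviz_format_error", parent = e)
    }
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warn(sprintf("no features found in %s; returning empty annotation.", path))
    return(empty_gene_annotation())
  }
  df$type <- tolower(as.character(df$type))
  df$Parent <- flatten_parent(df$Parent)

  is_gene <- df$type == "gene"
  is_exon <- df$type == "exon"

  # map every feature that can carry exons back to its owning gene
  if (format == "gtf") {
    df$.gene_key <- first_non_null(df, c("gene_id", "ID"))
  } else {
    id <- first_non_null(df, "ID")
    parent <- df$Parent
    key <- id
    # climb Parent chains (exon -> transcript -> gene), max depth 5
    gene_ids <- id[is_gene]
    resolve <- parent
    for (i in seq_len(5)) {
      unresolved <- !is.na(resolve) & !(resolve %in% gene_ids)
      if (!any(unresolved)) break
      up <- parent[match(resolve[unresolved], id)]
      resolve[unresolved] <- ifelse(is.na(up), resolve[unresolved], up)
      if (all(is.na(up))) break
    }
    df$.gene_key <- ifelse(is_gene, id, resolve)
  }

  genes <- df[is_gene, , drop = FALSE]
  exons <- df[is_exon, , drop = FALSE]

  if (!nrow(genes) && nrow(exons)) {
    # minimal files with exon features only: derive gene spans per gene key
    genes <- do.call(rbind, lapply(split(exons, exons$.gene_key), function(g) {
      out <- g[1, , drop = FALSE]
      out$start <- min(g$start)
      out$end <- max(g$end)
      out
    }))
  }
  if (!nrow(genes)) {
    warn(sprintf("no gene features in %s; returning empty annotation.", path))
    return(empty_gene_annotation())
  }

  gene_id_raw <- genes$.gene_key
  exon_split <- split(exons[, c("start", "end")], exons$.gene_key)

  merged_exons <- lapply(gene_id_raw, function(k) {
    ex <- exon_split[[k]]
    if (is.null(ex) || !nrow(ex)) return(tibble(start = numeric(),
                                                end = numeric()))
    rd <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    tibble(start = as.numeric(IRanges::start(rd)),
           end = as.numeric(IRanges::end(rd)))
  })

  symbol <- first_non_null(genes, c("Name", "gene_name", "symbol"))
  biotype <- first_non_null(genes, c("biotype", "gene_biotype", "gene_type"))
  strand <- as.character(genes$strand)
  strand[!strand %in% c("+", "-")] <- NA_character_

  out <- tibble(
    gene_id = sub("^gene:", "", as.character(gene_id_raw)),
    symbol = ifelse(is.na(symbol), sub("^gene:", "", gene_id_raw), symbol),
    chrom = normalise_chrom(genes$seqnames),
    start = as.numeric(genes$start),
    end = as.numeric(genes$end),
    strand = strand,
    biotype = as.character(biotype),
    exons = merged_exons
  )
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  structure(out, class = c("gene_annotation", class(tibble())),
            source = list(path = path, format = format))
}

#' Query genes overlapping a region
#'
#' Returns every gene whose span overlaps the 1-based inclusive window
#' `[start, end]` on `chrom`, optionally restricted to given biotypes,
#' ordered by start. Each overlapping gene appears exactly once.
#'
#' @param ann A `gene_annotation` from [load_gene_models()].
#' @param chrom Chromosome label (any style; normalised before comparison).
#' @param start,end Window bounds, `start <= end`.
#' @param biotypes Optional character vector (e.g. `"protein_coding"`).
#' @return A `gene_annotation` tibble (possibly empty).
#' @export
query_genes <- function(ann, chrom, start, end, biotypes = NULL) {
  if (start > end) {
    abort("query start must be <= end.", class = "locusviz_domain_error")
  }
  chrom <- normalise_chrom(chrom)
  hit <- ann$chrom == chrom & ann$start <= end & ann$end >= start
  if (!is.null(biotypes)) {
    hit <- hit & !is.na(ann$biotype) & ann$biotype %in% biotypes
  }
  out <- ann[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Pack genes into non-overlapping gene-track rows
#'
#' Greedy first-fit interval packing: genes are sorted by (window-clipped)
#' start and each is placed on the lowest row where its extent — the clipped
#' span widened by the label box — does not overlap any extent already on
#' that row. Labels sit left of the gene span by default and flip to the
#' right when the left extent would leave the window. With zero label widths
#' this packing is optimal: the number of rows equals the maximum
#' interval-overlap depth.
#'
#' @param genes A `gene_annotation` tibble (typically `locus$genes`).
#' @param window Numeric `c(start, end)` of the display window.
#' @param label_width_fn Function mapping a one-row gene tibble to a label
#'   width in genomic units. Default: `nchar(symbol) * char_width`.
#' @param max_rows Optional row cap; genes that would need more rows are
#'   reported in the `clipped` attribute instead of being placed.
#' @param char_width Per-character genomic width for the default label model;
#'   default 0.9% of the window width.
#' @return A `track_layout` tibble: the gene columns plus `row` (1 = top),
#'   `disp_start`/`disp_end` (span clipped to the window), `extent_start`/
#'   `extent_end` (span plus label box), `label_side`, and truncation flags.
#'   Attributes: `n_rows`, `clipped` (tibble of omitted genes), `window`.
#' @export
layout_gene_track <- function(genes, window, label_width_fn = NULL,
                              max_rows = NULL, char_width = NULL) {
  wstart <- as.numeric(window[1])
  wend <- as.numeric(window[2])
  width <- wend - wstart + 1
  char_width <- char_width %||% (0.009 * width)
  label_width_fn <- label_width_fn %||% function(g) {
    s <- g$symbol %||% ""
    if (is.na(s)) s <- ""
    nchar(s) * char_width
  }

  genes <- as_tibble(genes)
  genes <- genes[genes$start <= wend & genes$end >= wstart, , drop = FALSE]
  if (!nrow(genes)) {
    out <- structure(genes, class = c("track_layout", class(tibble())),
                     n_rows = 0L, clipped = genes, window = c(wstart, wend))
    return(out)
  }

  genes$disp_start <- pmax(genes$start, wstart)
  genes$disp_end <- pmin(genes$end, wend)
  genes$truncated_left <- genes$start < wstart
  genes$truncated_right <- genes$end > wend
  genes <- genes[order(genes$disp_start, genes$disp_end, genes$symbol), ,
                 drop = FALSE]

  n <- nrow(genes)
  extent_start <- extent_end <- numeric(n)
  label_side <- character(n)
  for (i in seq_len(n)) {
    lw <- as.numeric(label_width_fn(genes[i, ]))
    if (genes$disp_start[i] - lw >= wstart || lw == 0) {
      label_side[i] <- "left"
      extent_start[i] <- genes$disp_start[i] - lw
      extent_end[i] <- genes$disp_end[i]
    } else {
      label_side[i] <- "right"
      extent_start[i] <- genes$disp_start[i]
      extent_end[i] <- genes$disp_end[i] + lw
    }
  }
  extent_start <- pmax(extent_start, wstart)
  extent_end <- pmin(extent_end, wend)

  rows <- integer(n)
  occupied <- list()  # per row: 2-col matrix of (start, end)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (r in seq_along(occupied)) {
      occ <- occupied[[r]]
      if (!any(occ[, 1] <= extent_end[i] & occ[, 2] >= extent_start[i])) {
        occupied[[r]] <- rbind(occ, c(extent_start[i], extent_end[i]))
        rows[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      occupied[[length(occupied) + 1L]] <- matrix(
        c(extent_start[i], extent_end[i]), nrow = 1)
      rows[i] <- length(occupied)
    }
  }

  genes$row <- rows
  genes$extent_start <- extent_start
  genes$extent_end <- extent_end
  genes$label_side <- label_side

  clipped <- genes[0, , drop = FALSE]
  if (!is.null(max_rows) && any(rows > max_rows)) {
    clipped <- genes[rows > max_rows, , drop = FALSE]
    genes <- genes[rows <= max_rows, , drop = FALSE]
  }

  structure(genes, class = c("track_layout", class(tibble())),
            n_rows = if (nrow(genes)) max(genes$row) else 0L,
            clipped = clipped, window = c(wstart, wend))
}
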
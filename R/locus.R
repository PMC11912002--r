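# The locus object: a genomic window bundling a summary-statistics slice,
# an index variant, gene models and optional overlays in one coordinate frame.

#' Build a locus: a genomic window of summary statistics plus annotation
#'
#' Resolves a region specification to an explicit 1-based inclusive window,
#' slices `stats` to it, queries `annotation` for overlapping genes, and picks
#' the index variant (smallest p; ties broken by chromosome rank, then
#' position, then variant id, so output is deterministic). The region can be
#' given three ways: explicit `chrom`/`start`/`end`; a `gene` symbol plus
#' `flank` (window = gene span widened by `flank` on both sides); or a
#' `variant` id plus `flank` (window centred on the variant).
#'
#' @param stats A `sumstats` table ([read_summary_stats()] / [as_sumstats()]).
#' @param chrom,start,end Explicit window (1-based, inclusive).
#' @param gene Gene symbol (or gene id) to centre on; requires `annotation`.
#' @param variant Variant id to centre on.
#' @param flank Bases added to each side of a gene/variant spec
#'   (default 100000).
#' @param annotation Optional [load_gene_models()] gene annotation.
#' @param biotypes Optional character vector restricting genes by biotype
#'   (e.g. `"protein_coding"`).
#' @param index Optional variant id overriding the automatic min-p index
#'   variant.
#' @return A `locus` object: list with elements `chrom`, `start`, `end`,
#'   `data` (the stats slice), `index` (one-row tibble or `NULL`), `genes`,
#'   and `NULL` slots `ld`, `recomb`, `eqtl` filled by [attach_overlays()].
#' @examples
#' ss <- as_sumstats(data.frame(chrom = "7", pos = c(50, 150, 250),
#'                              p = c(0.5, 1e-8, 0.2)))
#' loc <- locus(ss, chrom = "7", start = 100, end = 200)
#' loc$index$pos  # 150
#' @seealso [attach_overlays()], [plot_locus()], [tidy.locus()]
#' @export
locus <- function(stats, chrom = NULL, start = NULL, end = NULL,
                  gene = NULL, variant = NULL, flank = 100000,
                  annotation = NULL, biotypes = NULL, index = NULL) {
  if (!inherits(stats, "sumstats")) stats <- as_sumstats(stats)

  if (!is.null(gene)) {
    if (is.null(annotation)) {
      abort("a gene-centred region requires `annotation`.",
            class = "locusviz_config_error")
    }
    hit <- annotation[annotation$symbol == gene | annotation$gene_id == gene, ]
    if (!nrow(hit)) {
      abort(sprintf("gene '%s' not found in annotation.", gene),
            class = "locusviz_lookup_error")
    }
    hit <- hit[1, ]
    chrom <- hit$chrom
    start <- max(1, hit$start - flank)
    end <- hit$end + flank
  } else if (!is.null(variant)) {
    if (!"id" %in% names(stats)) {
      abort("`stats` has no id column; cannot resolve a variant spec.",
            class = "locusviz_config_error")
    }
    hit <- stats[!is.na(stats$id) & stats$id == variant, ]
    if (!nrow(hit)) {
      abort(sprintf("variant '%s' not found in summary statistics.", variant),
            class = "locusviz_lookup_error")
    }
    chrom <- hit$chrom[1]
    start <- max(1, hit$pos[1] - flank)
    end <- hit$pos[1] + flank
  } else if (is.null(chrom) || is.null(start) || is.null(end)) {
    abort("specify a region as chrom/start/end, gene+flank, or variant+flank.",
          class = "locusviz_config_error")
  }

  chrom <- normalise_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (start > end) {
    abort("window start must be <= end.", class = "locusviz_domain_error")
  }

  dat <- as_tibble(stats)
  dat <- dat[dat$chrom == chrom & dat$pos >= start & dat$pos <= end, ,
             drop = FALSE]
  dat <- dat[order(dat$pos), , drop = FALSE]

  genes <- if (!is.null(annotation)) {
    query_genes(annotation, chrom, start, end, biotypes = biotypes)
  } else {
    empty_gene_annotation()
  }

  idx <- NULL
  if (nrow(dat) == 0) {
    warn(sprintf("locus %s:%s-%s contains zero variants.", chrom,
                 format(start, scientific = FALSE),
                 format(end, scientific = FALSE)))
  } else if (!is.null(index)) {
    hit <- which(!is.na(dat$id) & dat$id == index)
    if (!length(hit)) {
      abort(sprintf("index variant '%s' not inside the locus window.", index),
            class = "locusviz_lookup_error")
    }
    idx <- dat[hit[1], ]
  } else {
    idx <- dat[order_variants(dat)[1], ]
  }

  structure(
    list(chrom = chrom, start = start, end = end,
         data = dat, index = idx, genes = genes,
         ld = NULL, recomb = NULL, eqtl = NULL,
         source = attr(stats, "source")),
    class = "locus"
  )
}

# Deterministic variant ordering used for index selection and peak ties:
# ascending p, chromosome rank, position, then lexicographic id.
order_variants <- function(df) {
  id <- if ("id" %in% names(df)) df$id else rep("", nrow(df))
  order(df$p, chrom_rank(df$chrom), df$pos, id)
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("# locus %s:%s-%s\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE)))
  cat(sprintf("#   %d variant(s), %d gene(s)", nrow(x$data), nrow(x$genes)))
  if (!is.null(x$index)) {
    cat(sprintf("; index %s (p = %.3g)",
                if (!is.null(x$index$id)) x$index$id else
                  paste0(x$index$chrom, ":", x$index$pos),
                x$index$p))
  }
  cat("\n")
  overlays <- c(ld = !is.null(x$ld), recomb = !is.null(x$recomb),
                eqtl = !is.null(x$eqtl))
  if (any(overlays)) {
    cat("#   overlays:", paste(names(overlays)[overlays], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy a locus into one row per variant
#'
#' Returns the locus's summary-statistics slice with display columns added:
#' `logp` (`-log10(p)`, see [neglog10()]), `is_index`, and — when LD is
#' attached — `r2` and the binned `ld_cat` factor used for colouring.
#'
#' @param x A [locus()] object.
#' @param cap Passed to [neglog10()].
#' @param ... Unused.
#' @return A tibble with one row per variant in the window.
#' @method tidy locus
#' @export
tidy.locus <- function(x, cap = 300, ...) {
  dat <- x$data
  dat$logp <- neglog10(dat$p, cap = cap)
  dat$is_index <- FALSE
  if (!is.null(x$index) && nrow(dat)) {
    key <- paste(dat$chrom, dat$pos,
                 if ("id" %in% names(dat)) dat$id else "")
    ikey <- paste(x$index$chrom, x$index$pos,
                  if ("id" %in% names(dat)) x$index$id else "")
    dat$is_index <- key == ikey
  }
  if (!is.null(x$ld)) {
    if (!"r2" %in% names(dat)) {
      join_cols <- intersect("id", names(dat))
      dat <- left_join(dat, x$ld[, c("id", "r2")], by = join_cols)
    }
    dat$ld_cat <- ld_category(dat$r2, index = dat$is_index)
  }
  dat
}

#' One-row summaries of locusviz objects
#'
#' `glance()` methods give a one-row tibble describing a summary-statistics
#' table, a locus, or a peak set.
#'
#' @param x A `sumstats`, `locus` or `gwas_peaks` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance locus
#' @export
glance.locus <- function(x, ...) {
  tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    width = x$end - x$start + 1,
    n_variants = nrow(x$data),
    n_genes = nrow(x$genes),
    index_id = if (!is.null(x$index) && "id" %in% names(x$index))
      x$index$id else NA_character_,
    index_pos = if (!is.null(x$index)) x$index$pos else NA_real_,
    min_p = if (nrow(x$data)) min(x$data$p) else NA_real_,
    has_ld = !is.null(x$ld),
    has_recomb = !is.null(x$recomb),
    has_eqtl = !is.null(x$eqtl)
  )
}

#' Write a locus's summary-statistics slice as TSV
#'
#' @param x A [locus()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus <- function(x, path) {
  write_summary_stats(as_sumstats(x$data, source = "locus"), path)
}
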
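# Greedy peak scanning of genome-wide summary statistics.
#
# Algorithm (select-and-exclude): repeatedly take the unmasked record with
# smallest p below the cutoff, emit it as a peak, and mask every record on the
# same chromosome within +/- span/2 of it. Implemented as one sort by p over
# the below-cutoff candidates plus a nearest-accepted-peak distance check per
# candidate, so runtime is dominated by the sort even on multi-million-row
# inputs.

#' Scan summary statistics for independent association peaks
#'
#' Greedy distance-pruned peak selection: the most significant remaining
#' variant below `p_cutoff` becomes the next peak and masks all variants on
#' its chromosome within `span/2` of it; repeat until nothing is left below
#' the cutoff (or `max_peaks` is reached). Ties in p are broken by chromosome
#' rank, then position, then variant id, so output is deterministic.
#'
#' @param stats A `sumstats` table.
#' @param p_cutoff Significance cutoff, strictly between 0 and 1. Default
#'   `5e-8`, the conventional genome-wide level.
#' @param span Full width of the exclusion window in bases (masking is
#'   `+/- span/2` around each peak). Default 1 Mb, matching the default
#'   plotting window so peak lists and batch plots share one parameter.
#' @param max_peaks Optional cap on the number of peaks returned.
#' @return A `gwas_peaks` tibble ordered by rank (ascending p) with columns
#'   `rank`, `chrom`, `pos`, `id` (if present), `p`, `window_start`,
#'   `window_end` (the exclusion interval used). Attributes `p_cutoff` and
#'   `span` record the parameters. Zero qualifying variants give an empty
#'   table, not an error.
#' @examples
#' ss <- simulate_gwas(5000, c("1" = 1e7),
#'                     peaks = peak_spec("1", 5e6, height = 10), seed = 1)
#' quickpeak(ss, p_cutoff = 1e-6, span = 1e6)
#' @seealso [peaks_to_loci()], [write_peaks()]
#' @export
quickpeak <- function(stats, p_cutoff = 5e-8, span = 1e6, max_peaks = Inf) {
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1 ||
      p_cutoff <= 0 || p_cutoff >= 1) {
    abort("`p_cutoff` must lie strictly between 0 and 1.",
          class = "locusviz_domain_error")
  }
  if (!is.numeric(span) || span <= 0) {
    abort("`span` must be > 0.", class = "locusviz_domain_error")
  }
  if (!inherits(stats, "sumstats")) stats <- as_sumstats(stats)
  df <- as_tibble(stats)
  has_id <- "id" %in% names(df)

  cand <- df[!is.na(df$p) & df$p < p_cutoff, , drop = FALSE]
  half <- span / 2
  if (nrow(cand)) {
    cand <- cand[order_variants(cand), , drop = FALSE]
    accepted <- new.env(parent = emptyenv())  # chrom -> numeric positions
    keep <- logical(nrow(cand))
    n_found <- 0L
    for (i in seq_len(nrow(cand))) {
      if (n_found >= max_peaks) break
      ch <- cand$chrom[i]
      pos <- cand$pos[i]
      acc <- accepted[[ch]]
      if (is.null(acc) || all(abs(acc - pos) > half)) {
        accepted[[ch]] <- c(acc, pos)
        keep[i] <- TRUE
        n_found <- n_found + 1L
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }

  out <- tibble(
    rank = seq_len(nrow(cand)),
    chrom = cand$chrom,
    pos = cand$pos,
    p = cand$p,
    window_start = cand$pos - half,
    window_end = cand$pos + half
  )
  if (has_id) out <- tibble::add_column(out, id = cand$id, .after = "pos")
  structure(out, class = c("gwas_peaks", class(tibble())),
            p_cutoff = p_cutoff, span = span)
}

#' Expand peaks into fixed-width plotting loci
#'
#' Builds one [locus()] per peak, centred on the peak variant with total
#' window width `window_width`. Windows running off the chromosome start are
#' clipped at 1 with the width preserved toward the right. The peak variant
#' becomes the locus index variant.
#'
#' @param peaks A `gwas_peaks` table from [quickpeak()].
#' @param stats The `sumstats` table the peaks came from.
#' @param annotation Optional gene annotation for the gene tracks.
#' @param window_width Total window width in bases (default 1 Mb).
#' @return A list of `locus` objects, one per peak, in rank order.
#' @export
peaks_to_loci <- function(peaks, stats, annotation = NULL,
                          window_width = 1e6) {
  if (window_width <= 0) {
    abort("`window_width` must be > 0.", class = "locusviz_domain_error")
  }
  purrr::pmap(
    list(peaks$chrom, peaks$pos,
         if ("id" %in% names(peaks)) peaks$id else
           rep(NA_character_, nrow(peaks))),
    function(chrom, pos, id) {
      start <- pos - floor(window_width / 2) + 1
      if (start < 1) start <- 1
      end <- start + window_width - 1
      locus(stats, chrom = chrom, start = start, end = end,
            annotation = annotation,
            index = if (!is.na(id)) id else NULL)
    }
  )
}

#' @rdname glance.locus
#' @method glance gwas_peaks
#' @export
glance.gwas_peaks <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    p_cutoff = attr(x, "p_cutoff"),
    span = attr(x, "span"),
    min_p = if (nrow(x)) min(x$p) else NA_real_,
    n_chrom = length(unique(x$chrom))
  )
}

#' Write a peak table as TSV, or its exclusion windows as BED
#'
#' `write_peaks()` emits the tab-delimited peak list (chrom, pos, id, p,
#' rank). `peaks_to_bed()` writes the exclusion windows in BED format,
#' converted to 0-based half-open coordinates on write and clipped at the
#' chromosome start.
#'
#' @param peaks A `gwas_peaks` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  cols <- intersect(c("chrom", "pos", "id", "p", "rank"), names(peaks))
  readr::write_tsv(as_tibble(peaks)[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
peaks_to_bed <- function(peaks, path) {
  bed <- tibble(
    chrom = peaks$chrom,
    start = pmax(0, peaks$window_start - 1),  # 1-based -> 0-based half-open
    end = peaks$window_end,
    name = if ("id" %in% names(peaks)) peaks$id else
      paste0("peak", peaks$rank),
    score = peaks$rank
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
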
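# Synthetic data generators: GWAS summary statistics with planted peaks,
# gene models, LD tables, recombination tracks and eQTL tables. Every
# generator is a pure function of (parameters, seed), and every writer
# round-trips through the corresponding reader, so the whole package is
# testable with no downloads.
#
# The noise model is a pragmatic stand-in, not population genetics: the
# background is p ~ Uniform(0,1) (equivalently -log10 p ~ Exponential with
# mean log10(e) ~ 0.4343), and a planted association adds an exponentially
# decaying -log10 p envelope with Gaussian jitter (sd 0.25) on the -log10
# scale. It produces realistic-looking peaks without modelling LD-driven
# p-value correlation.

#' Specify a planted association peak
#'
#' @param chrom Chromosome label.
#' @param causal_pos Position of the causal variant.
#' @param height Target `-log10(p)` at the causal position (> 0).
#' @param tau Decay scale in bases: the signal falls off as
#'   `height * exp(-d / tau)` with distance `d` (> 0).
#' @return A one-row tibble usable in the `peaks` argument of
#'   [simulate_gwas()]; rows may be bound together for multiple peaks.
#' @export
peak_spec <- function(chrom, causal_pos, height = 10, tau = 50000) {
  stopifnot(height > 0, tau > 0)
  tibble(chrom = normalise_chrom(chrom), causal_pos = causal_pos,
         height = height, tau = tau)
}

#' Simulate GWAS summary statistics with planted peaks
#'
#' Variant positions are uniform over the chromosomes (chromosome chosen
#' proportional to length). Background `-log10(p)` is `-log10(U)` with
#' `U ~ Uniform(0, 1)`. For variants within `5 * tau` of a planted causal
#' position, the displayed `-log10(p)` is the maximum of the background and
#' the decaying signal `height * exp(-d / tau) + N(0, 0.25^2)`, floored at 0.
#'
#' @param n_snps Number of variants (> 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths, e.g.
#'   `c("1" = 2e7, "2" = 1.5e7)`.
#' @param peaks Optional tibble of [peak_spec()] rows.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return A `sumstats` tibble with `chrom`, `pos`, `p`, `id` (`snp_...`),
#'   `direction` and `typed` columns, sorted by `(chrom, pos)`.
#' @examples
#' ss <- simulate_gwas(1000, c("1" = 1e7),
#'                     peaks = peak_spec("1", 5e6, height = 9), seed = 42)
#' min(ss$p)
#' @export
simulate_gwas <- function(n_snps, chrom_lengths, peaks = NULL, seed = 42) {
  stopifnot(n_snps > 0, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  chroms <- normalise_chrom(names(chrom_lengths))
  withr::with_seed(seed, {
    ch <- sample(seq_along(chroms), n_snps, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(stats::runif(n_snps, min = 1,
                              max = chrom_lengths[ch] + 1))
    nlp <- -log10(stats::runif(n_snps))
    if (!is.null(peaks) && nrow(peaks)) {
      for (k in seq_len(nrow(peaks))) {
        on_chr <- chroms[ch] == peaks$chrom[k]
        d <- abs(pos - peaks$causal_pos[k])
        hit <- on_chr & d <= 5 * peaks$tau[k]
        if (any(hit)) {
          signal <- peaks$height[k] * exp(-d[hit] / peaks$tau[k]) +
            stats::rnorm(sum(hit), 0, 0.25)
          nlp[hit] <- pmax(nlp[hit], signal, 0)
        }
      }
    }
    df <- tibble(
      chrom = chroms[ch],
      pos = pos,
      p = 10^(-nlp),
      direction = sample(c(-1, 1), n_snps, replace = TRUE),
      typed = sample(c(TRUE, FALSE), n_snps, replace = TRUE,
                     prob = c(0.3, 0.7))
    )
  })
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
  df <- tibble::add_column(df, id = sprintf("snp_%06d", seq_len(nrow(df))),
                           .after = "pos")
  new_sumstats(df, source = sprintf("simulate_gwas(seed=%d)", seed))
}

#' Simulate gene models (optionally written as GFF3)
#'
#' Random non-degenerate gene spans inside `window` on `chrom`, each with
#' 1-10 exons contained in its span (first and last exon touch the span
#' ends), random strand, and biotype drawn from protein_coding / lincRNA /
#' pseudogene. The output round-trips through [write_gff3()] and
#' [load_gene_models()].
#'
#' @param chrom Chromosome label.
#' @param window Numeric `c(start, end)` the genes are drawn in.
#' @param n_genes Number of genes (>= 0).
#' @param seed Integer seed.
#' @param path Optional path; when given, the annotation is also written
#'   there as GFF3.
#' @return A `gene_annotation` tibble.
#' @export
simulate_genes <- function(chrom, window, n_genes, seed = 42, path = NULL) {
  stopifnot(n_genes >= 0, length(window) == 2, window[1] <= window[2])
  chrom <- normalise_chrom(chrom)
  if (n_genes == 0) {
    ann <- empty_gene_annotation()
  } else {
    width <- window[2] - window[1] + 1
    ann <- withr::with_seed(seed, {
      rows <- lapply(seq_len(n_genes), function(i) {
        span_w <- max(200, floor(stats::runif(1, 0.01, 0.15) * width))
        gstart <- floor(stats::runif(1, window[1],
                                     max(window[1] + 1, window[2] - span_w)))
        gend <- min(gstart + span_w, window[2])
        n_ex <- sample(1:10, 1)
        # 2*n_ex sorted breakpoints inside the span; first/last pinned to ends
        bp <- sort(sample(seq(gstart, gend), min(2 * n_ex, gend - gstart + 1)))
        if (length(bp) %% 2 == 1) bp <- bp[-length(bp)]
        if (length(bp) < 2) bp <- c(gstart, gend)
        bp[1] <- gstart
        bp[length(bp)] <- gend
        ex <- tibble(start = bp[seq(1, length(bp), by = 2)],
                     end = bp[seq(2, length(bp), by = 2)])
        rd <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
        ex <- tibble(start = as.numeric(IRanges::start(rd)),
                     end = as.numeric(IRanges::end(rd)))
        tibble(
          gene_id = sprintf("SIMG%04d", i),
          symbol = sprintf("GENE%d", i),
          chrom = chrom,
          start = gstart, end = gend,
          strand = sample(c("+", "-"), 1),
          biotype = sample(c("protein_coding", "lincRNA", "pseudogene"), 1,
                           prob = c(0.6, 0.25, 0.15)),
          exons = list(ex)
        )
      })
      bind_rows(rows)
    })
    ann <- ann[order(ann$start), , drop = FALSE]
    ann <- structure(ann, class = c("gene_annotation", class(tibble())),
                     source = list(path = sprintf("simulate_genes(seed=%d)",
                                                  seed),
                                   format = "memory"))
  }
  if (!is.null(path)) write_gff3(ann, path)
  ann
}

#' Write a gene annotation as GFF3
#'
#' One `gene` feature per gene plus its `exon` features (Parent = gene);
#' consumable by [load_gene_models()].
#'
#' @param ann A `gene_annotation` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    strand <- if (is.na(g$strand)) "." else g$strand
    lines <- c(lines, sprintf(
      "%s\tlocusviz\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=gene:%s;Name=%s;biotype=%s",
      g$chrom, g$start, g$end, strand, g$gene_id, g$symbol, g$biotype))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tlocusviz\texon\t%.0f\t%.0f\t.\t%s\t.\tParent=gene:%s",
        g$chrom, ex$start[j], ex$end[j], strand, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an LD table around a locus index variant
#'
#' `r2 = clip(exp(-d / tau) + N(0, 0.05^2), 0, 1)` for each locus variant at
#' distance `d` from the index variant; the index itself gets exactly 1.
#'
#' @param locus A [locus()] object with an index variant and id column.
#' @param index_id Index variant id; defaults to the locus index variant.
#' @param tau Decay scale in bases (default 50000).
#' @param seed Integer seed.
#' @return An `ld_table` tibble.
#' @export
simulate_ld <- function(locus, index_id = NULL, tau = 50000, seed = 42) {
  stopifnot(inherits(locus, "locus"), "id" %in% names(locus$data))
  index_id <- index_id %||% locus$index$id
  ipos <- locus$data$pos[match(index_id, locus$data$id)]
  if (is.na(ipos)) {
    abort(sprintf("index variant '%s' not in locus.", index_id),
          class = "locusviz_lookup_error")
  }
  d <- abs(locus$data$pos - ipos)
  r2 <- withr::with_seed(seed, {
    pmin(pmax(exp(-d / tau) + stats::rnorm(length(d), 0, 0.05), 0), 1)
  })
  r2[locus$data$id == index_id] <- 1
  structure(tibble(id = locus$data$id, r2 = r2),
            class = c("ld_table", class(tibble())), index_id = index_id)
}

#' Simulate a recombination-rate track (optionally written as bedGraph)
#'
#' Contiguous intervals covering `[1, length]` with lognormal rates
#' (meanlog 0, sdlog 1, i.e. a median of 1 cM/Mb).
#'
#' @param chrom Chromosome label.
#' @param length Chromosome length in bases.
#' @param n_intervals Number of contiguous intervals (>= 1).
#' @param seed Integer seed.
#' @param path Optional path; when given, also written as bedGraph
#'   (0-based half-open on write).
#' @return A `recomb_track` tibble covering `[1, length]` exactly.
#' @export
simulate_recomb <- function(chrom, length, n_intervals, seed = 42,
                            path = NULL) {
  stopifnot(n_intervals >= 1, length >= n_intervals)
  chrom <- normalise_chrom(chrom)
  track <- withr::with_seed(seed, {
    cuts <- if (n_intervals > 1) {
      sort(sample(seq(2, length), n_intervals - 1))
    } else numeric(0)
    starts <- c(1, cuts)
    ends <- c(cuts - 1, length)
    tibble(chrom = chrom, start = starts, end = ends,
           rate = stats::rlnorm(n_intervals, meanlog = 0, sdlog = 1))
  })
  track <- structure(track, class = c("recomb_track", class(tibble())),
                     source = sprintf("simulate_recomb(seed=%d)", seed))
  if (!is.null(path)) write_bedgraph(track, path)
  track
}

#' Write a recombination track as bedGraph
#'
#' Converts the internal 1-based inclusive intervals to bedGraph's 0-based
#' half-open coordinates on write; consumable by [load_recomb()].
#'
#' @param track A `recomb_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f\t%g", track$chrom, track$start - 1,
                     track$end, track$rate), path)
  invisible(path)
}

#' Simulate an eQTL table for a locus
#'
#' Each locus variant gets an eQTL p-value that mirrors (with noise) its
#' GWAS signal, a random effect direction, and the given target gene/tissue.
#'
#' @param locus A [locus()] object.
#' @param gene Target gene symbol.
#' @param tissue Tissue label.
#' @param seed Integer seed.
#' @return An `eqtl_table` tibble.
#' @export
simulate_eqtl <- function(locus, gene = "GENE1", tissue = "whole_blood",
                          seed = 42) {
  stopifnot(inherits(locus, "locus"))
  n <- nrow(locus$data)
  withr::with_seed(seed, {
    nlp <- pmax(neglog10(locus$data$p) * stats::runif(n, 0.3, 0.9) +
                  stats::rnorm(n, 0, 0.5), 0)
    structure(tibble(
      id = locus$data$id,
      pos = locus$data$pos,
      p = 10^(-nlp),
      direction = sample(c(-1, 1), n, replace = TRUE),
      gene = gene,
      tissue = tissue
    ), class = c("eqtl_table", class(tibble())), source = "simulate_eqtl")
  })
}

#' Write LD or eQTL tables as TSV
#'
#' @param x An `ld_table` or `eqtl_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(x, path) {
  readr::write_tsv(as_tibble(x)[, c("id", "r2")], path)
  invisible(path)
}

#' @rdname write_ld
#' @export
write_eqtl <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
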
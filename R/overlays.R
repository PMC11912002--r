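# Overlays: LD r2 tables, recombination-rate tracks and eQTL tables, attached
# to a locus in its own coordinate frame. File readers here; the pluggable
# cached provider contract lives in provider.R.

LD_LEVELS <- c("none", "0.0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8",
               "0.8-1.0", "index")

#' Bin r-squared values into LD display categories
#'
#' Maps each r2 to one of the five classic 0.2-wide LD bins (left-closed,
#' top bin `[0.8, 1.0]` closed), with missing values in a distinct `"none"`
#' category and the index variant in its own `"index"` category. The result
#' is an ordered factor so colour scales sort correctly.
#'
#' @param r2 Numeric vector in `[0, 1]`; `NA` allowed.
#' @param index Logical vector (recycled) flagging the index variant.
#' @return Ordered factor with levels
#'   `none < 0.0-0.2 < ... < 0.8-1.0 < index`.
#' @examples
#' ld_category(c(0.85, 0.2, NA), index = c(FALSE, FALSE, FALSE))
#' @export
ld_category <- function(r2, index = FALSE) {
  if (is.null(r2)) r2 <- rep(NA_real_, max(length(index), 1))
  r2 <- as.numeric(r2)
  bad <- !is.na(r2) & (r2 < 0 | r2 > 1)
  if (any(bad)) {
    abort(sprintf("r2 values must lie in [0, 1]; got %g.", r2[bad][1]),
          class = "locusviz_domain_error")
  }
  index <- rep_len(as.logical(index), length(r2))
  bin <- findInterval(r2, c(0.2, 0.4, 0.6, 0.8)) + 2L  # 2..6
  lab <- LD_LEVELS[bin]
  lab[is.na(r2)] <- "none"
  lab[index] <- "index"
  factor(lab, levels = LD_LEVELS, ordered = TRUE)
}

#' Load an LD table (variant id to r-squared against an index variant)
#'
#' Reads a delimited file with a variant-id column and an r2 column
#' (recognised names: `id`/`rsid`/`variant`/`snp` and `r2`/`rsquare`/`R2`,
#' case-insensitive, or positions 1 and 2 when unnamed). Rows with r2 outside
#' `[0, 1]` are dropped with a warning. If `index_id` is given and absent
#' from the file it is added with r2 = 1 (r2 of a variant with itself).
#'
#' @param path Path to the delimited file.
#' @param index_id Optional id of the index variant the r2 values refer to.
#' @param delim Delimiter; `NULL` auto-detects.
#' @return An `ld_table` tibble with columns `id`, `r2` and attribute
#'   `index_id`.
#' @export
load_ld <- function(path, index_id = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("LD file not found: %s", path),
          class = "locusviz_io_error")
  }
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  nml <- tolower(names(df))
  id_col <- which(nml %in% c("id", "rsid", "variant", "snp", "rs_number"))[1]
  r2_col <- which(nml %in% c("r2", "rsquare", "rsquared", "r.squared"))[1]
  if (is.na(id_col) || is.na(r2_col)) {
    abort(sprintf("LD file %s must have variant-id and r2 columns.", path),
          class = "locusviz_config_error")
  }
  out <- tibble(id = as.character(df[[id_col]]),
                r2 = suppressWarnings(as.numeric(df[[r2_col]])))
  bad <- is.na(out$r2) | out$r2 < 0 | out$r2 > 1
  if (any(bad)) {
    warn(sprintf("load_ld: dropped %d row(s) with r2 outside [0, 1].",
                 sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(index_id) && !index_id %in% out$id) {
    out <- bind_rows(out, tibble(id = index_id, r2 = 1))
  }
  structure(out, class = c("ld_table", class(tibble())), index_id = index_id)
}

#' Load a recombination-rate track from bedGraph or bigWig
#'
#' bedGraph input is 0-based half-open and converted to the package's
#' 1-based inclusive frame on read. Intervals overlapping an earlier interval
#' are resolved last-wins (the later line overrides the overlapped part) with
#' a warning; abutting intervals are kept as-is, never merged.
#'
#' @param path Path to the track file.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"bigwig"`.
#' @return A `recomb_track` tibble with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `rate` (cM/Mb), sorted and non-overlapping per
#'   chromosome.
#' @export
load_recomb <- function(path, format = c("auto", "bedgraph", "bigwig")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("recombination track not found: %s", path),
          class = "locusviz_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", tolower(path))) "bigwig"
    else "bedgraph"
  }
  gr <- tryCatch(
    if (format == "bigwig") rtracklayer::import.bw(path)
    else rtracklayer::import(path, format = "bedGraph"),
    error = function(e) {
      abort(sprintf("failed to parse %s as %s: %s", path, format,
                    conditionMessage(e)),
            class = "locusviz_format_error", parent = e)
    }
  )
  df <- as.data.frame(gr)  # rtracklayer already yields 1-based inclusive
  track <- tibble(chrom = normalise_chrom(df$seqnames),
                  start = as.numeric(df$start),
                  end = as.numeric(df$end),
                  rate = as.numeric(df$score))
  if (any(track$rate < 0, na.rm = TRUE)) {
    warn("load_recomb: negative rates clamped to 0.")
    track$rate <- pmax(track$rate, 0)
  }
  track <- resolve_overlaps_last_wins(track)
  structure(track, class = c("recomb_track", class(tibble())),
            source = path)
}

# Later intervals override overlapped parts of earlier ones (file order).
resolve_overlaps_last_wins <- function(track) {
  pieces <- lapply(split(track, track$chrom), function(tr) {
    kept <- tr[0, , drop = FALSE]
    n_conflict <- 0L
    for (i in seq_len(nrow(tr))) {
      s <- tr$start[i]; e <- tr$end[i]
      ov <- kept$start <= e & kept$end >= s
      if (any(ov)) {
        n_conflict <- n_conflict + 1L
        new_kept <- kept[!ov, , drop = FALSE]
        for (j in which(ov)) {
          k <- kept[j, , drop = FALSE]
          if (k$start < s) {
            left <- k; left$end <- s - 1
            new_kept <- rbind(new_kept, left)
          }
          if (k$end > e) {
            right <- k; right$start <- e + 1
            new_kept <- rbind(new_kept, right)
          }
        }
        kept <- new_kept
      }
      kept <- rbind(kept, tr[i, , drop = FALSE])
    }
    attr(kept, "n_conflict") <- n_conflict
    kept
  })
  n_conflict <- sum(vapply(pieces, function(p) attr(p, "n_conflict"),
                           integer(1)))
  if (n_conflict > 0) {
    warn(sprintf(
      "load_recomb: %d overlapping interval(s) resolved last-wins.",
      n_conflict))
  }
  out <- bind_rows(pieces)
  out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
}

#' Point-query a recombination track
#'
#' @param track A `recomb_track`.
#' @param chrom Chromosome label.
#' @param pos Numeric vector of positions.
#' @return Rate (cM/Mb) at each position; `NA` outside track coverage.
#' @export
recomb_rate_at <- function(track, chrom, pos) {
  chrom <- normalise_chrom(chrom)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(tr)) return(rep(NA_real_, length(pos)))
  tr <- tr[order(tr$start), , drop = FALSE]
  i <- findInterval(pos, tr$start)
  out <- rep(NA_real_, length(pos))
  inside <- i >= 1 & pos <= tr$end[pmax(i, 1)]
  out[inside] <- tr$rate[i[inside]]
  out
}

#' Load an eQTL table
#'
#' Delimited file with columns (flexibly named) variant `id`, `pos`, `p`,
#' effect `direction`, target `gene` and `tissue`.
#'
#' @param path Path to the delimited file.
#' @param delim Delimiter; `NULL` auto-detects.
#' @return An `eqtl_table` tibble.
#' @export
load_eqtl <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("eQTL file not found: %s", path),
          class = "locusviz_io_error")
  }
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  nml <- tolower(names(df))
  pick <- function(cands) {
    j <- which(nml %in% cands)[1]
    if (is.na(j)) NULL else df[[j]]
  }
  id <- pick(c("id", "rsid", "variant", "snp"))
  pos <- pick(c("pos", "position", "bp"))
  p <- pick(c("p", "pvalue", "p_value", "pval"))
  if (is.null(id) || is.null(pos) || is.null(p)) {
    abort(sprintf("eQTL file %s needs id, pos and p columns.", path),
          class = "locusviz_config_error")
  }
  out <- tibble(
    id = as.character(id),
    pos = as.numeric(pos),
    p = as.numeric(p),
    direction = parse_direction(pick(c("direction", "effect", "beta_sign",
                                       "sign")) %||% rep(0, nrow(df))),
    gene = as.character(pick(c("gene", "target", "gene_symbol")) %||%
                          rep(NA_character_, nrow(df))),
    tissue = as.character(pick("tissue") %||% rep(NA_character_, nrow(df)))
  )
  bad <- is.na(out$p) | out$p < 0 | out$p > 1
  if (any(bad)) {
    warn(sprintf("load_eqtl: dropped %d row(s) with invalid p.", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  structure(out, class = c("eqtl_table", class(tibble())), source = path)
}

#' Attach LD, recombination and eQTL overlays to a locus
#'
#' Additive: the locus's variant records are never modified; LD joins an `r2`
#' column by variant id, the recombination track is clipped to the window as
#' piecewise-constant segments, and the eQTL table is filtered to the window.
#'
#' @param locus A [locus()] object.
#' @param ld Optional `ld_table` (or path, loaded via [load_ld()]).
#' @param recomb Optional `recomb_track` (or path, via [load_recomb()]). The
#'   track must cover the locus chromosome, otherwise a chromosome-mismatch
#'   error is raised.
#' @param eqtl Optional `eqtl_table` (or path, via [load_eqtl()]).
#' @return The locus with `ld`, `recomb` and/or `eqtl` slots populated.
#' @export
attach_overlays <- function(locus, ld = NULL, recomb = NULL, eqtl = NULL) {
  stopifnot(inherits(locus, "locus"))
  if (!is.null(ld)) {
    if (is.character(ld)) {
      ld <- load_ld(ld, index_id = if (!is.null(locus$index) &&
                                       "id" %in% names(locus$index))
        locus$index$id else NULL)
    }
    locus$ld <- ld
  }
  if (!is.null(recomb)) {
    if (is.character(recomb)) recomb <- load_recomb(recomb)
    tr <- recomb[recomb$chrom == locus$chrom, , drop = FALSE]
    if (!nrow(tr)) {
      abort(sprintf(
        "recombination track has no intervals on chromosome %s.",
        locus$chrom), class = "locusviz_join_error")
    }
    tr <- tr[tr$start <= locus$end & tr$end >= locus$start, , drop = FALSE]
    tr$start <- pmax(tr$start, locus$start)
    tr$end <- pmin(tr$end, locus$end)
    locus$recomb <- tr[order(tr$start), , drop = FALSE]
  }
  if (!is.null(eqtl)) {
    if (is.character(eqtl)) eqtl <- load_eqtl(eqtl)
    locus$eqtl <- eqtl[!is.na(eqtl$pos) & eqtl$pos >= locus$start &
                         eqtl$pos <= locus$end, , drop = FALSE]
  }
  locus
}
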
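# Independent brute-force oracles. These deliberately re-derive expected
# results with the simplest possible algorithms (repeated scans, sweeps,
# explicit histograms) and share no code with the implementations they check.

# chromosome ordering re-derived for the oracle
oracle_chrom_key <- function(ch) {
  k <- suppressWarnings(as.numeric(ch))
  k[ch == "X"] <- 23
  k[ch == "Y"] <- 24
  k[ch == "MT"] <- 25
  if (any(is.na(k))) {
    others <- sort(unique(ch[is.na(k)]))
    k[is.na(k)] <- 2000 + match(ch[is.na(k)], others)
  }
  k
}

# Literal greedy select-and-exclude: full rescan of every unmasked record at
# each step. O(n * peaks); fine for oracle-sized inputs.
oracle_quickpeak <- function(df, p_cutoff, span, max_peaks = Inf) {
  df <- as.data.frame(df)
  id <- if ("id" %in% names(df)) df$id else rep("", nrow(df))
  masked <- rep(FALSE, nrow(df))
  picked <- integer(0)
  repeat {
    if (length(picked) >= max_peaks) break
    elig <- which(!masked & !is.na(df$p) & df$p < p_cutoff)
    if (!length(elig)) break
    o <- elig[order(df$p[elig], oracle_chrom_key(df$chrom[elig]),
                    df$pos[elig], id[elig])]
    j <- o[1]
    picked <- c(picked, j)
    masked <- masked | (df$chrom == df$chrom[j] &
                          abs(df$pos - df$pos[j]) <= span / 2)
  }
  out <- df[picked, c("chrom", "pos", "p"), drop = FALSE]
  if ("id" %in% names(df)) out$id <- df$id[picked]
  rownames(out) <- NULL
  out
}

# every pair of peaks on the same chromosome must be > span/2 apart
oracle_check_exclusion <- function(peaks, span) {
  if (nrow(peaks) < 2) return(TRUE)
  ok <- TRUE
  for (i in seq_len(nrow(peaks) - 1)) {
    for (j in seq(i + 1, nrow(peaks))) {
      if (peaks$chrom[i] == peaks$chrom[j] &&
          abs(peaks$pos[i] - peaks$pos[j]) <= span / 2) ok <- FALSE
    }
  }
  ok
}

# maximum overlap depth of 1-based inclusive intervals (sweep line)
oracle_max_depth <- function(start, end) {
  if (!length(start)) return(0L)
  ev <- rbind(cbind(start, 1), cbind(end + 1, -1))
  ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
  max(cumsum(ev[, 2]))
}

# explicit histogram of r2 values over the five LD bins plus NA
oracle_ld_histogram <- function(r2) {
  counts <- c("none" = sum(is.na(r2)))
  lo <- c(0, 0.2, 0.4, 0.6, 0.8)
  hi <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  labs <- c("0.0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1.0")
  for (b in 1:5) {
    inside <- !is.na(r2) & r2 >= lo[b] &
      (if (b < 5) r2 < hi[b] else r2 <= hi[b])
    counts[labs[b]] <- sum(inside)
  }
  counts
}

# integral (rate x covered bases) of raw track intervals over [s, e]
oracle_track_integral <- function(track, chrom, s, e) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(tr))) {
    cov <- min(tr$end[i], e) - max(tr$start[i], s) + 1
    if (cov > 0) total <- total + cov * tr$rate[i]
  }
  total
}

# brute-force region overlap scan over all genes
oracle_overlap_query <- function(ann, chrom, s, e) {
  hit <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    hit[i] <- ann$chrom[i] == chrom && ann$start[i] <= e && ann$end[i] >= s
  }
  sort(ann$gene_id[hit])
}

# plain record view for comparisons: canonical columns, no extra attributes
peak_records <- function(x) {
  df <- as.data.frame(x)[, c("chrom", "pos", "p", "id"), drop = FALSE]
  df <- data.frame(lapply(df, unname), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
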
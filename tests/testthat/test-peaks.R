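# Peak scanner: greedy select-and-exclude semantics, oracle equivalence,
# monotonicity, determinism, and locus expansion.

test_that("a single sub-threshold record yields exactly one peak", {
  ss <- as_sumstats(data.frame(chrom = "1", pos = 1000, p = 1e-9,
                               id = "rs1"))
  pk <- quickpeak(ss, p_cutoff = 5e-8, span = 1e6)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$id, "rs1")
  expect_equal(pk$rank, 1L)
})

test_that("a nearby weaker signal is masked by the stronger peak", {
  ss <- as_sumstats(data.frame(chrom = "1", pos = c(1e6, 1.1e6),
                               p = c(1e-10, 1e-9),
                               id = c("rs_strong", "rs_weak")))
  pk <- quickpeak(ss, p_cutoff = 5e-8, span = 1e6)
  expect_equal(pk$id, "rs_strong")
  # beyond span/2 the weaker record survives
  pk2 <- quickpeak(ss, p_cutoff = 5e-8, span = 1.9e5)
  expect_equal(pk2$id, c("rs_strong", "rs_weak"))
})

test_that("masking is strictly inclusive at distance span/2", {
  ss <- as_sumstats(data.frame(chrom = "1",
                               pos = c(1e6, 1e6 + 5e5, 1e6 + 5e5 + 1),
                               p = c(1e-12, 1e-10, 1e-11),
                               id = c("a", "b", "c")))
  pk <- quickpeak(ss, p_cutoff = 1e-6, span = 1e6)
  # b is exactly span/2 away -> masked; c is span/2 + 1 -> kept
  expect_equal(pk$id, c("a", "c"))
})

test_that("no record below the cutoff gives an empty table, not an error", {
  ss <- as_sumstats(data.frame(chrom = "1", pos = 1:5, p = rep(0.5, 5)))
  pk <- quickpeak(ss, p_cutoff = 5e-8)
  expect_equal(nrow(pk), 0)
  expect_s3_class(pk, "gwas_peaks")
})

test_that("invalid cutoff and span are rejected", {
  ss <- tiny_stats()
  expect_error(quickpeak(ss, p_cutoff = 1), class = "locusviz_domain_error")
  expect_error(quickpeak(ss, p_cutoff = 0), class = "locusviz_domain_error")
  expect_error(quickpeak(ss, span = -5), class = "locusviz_domain_error")
})

test_that("three well-separated planted peaks are recovered exactly", {
  planted <- dplyr::bind_rows(
    peak_spec("1", 2e6, height = 10, tau = 5e4),
    peak_spec("1", 6e6, height = 11, tau = 5e4),
    peak_spec("2", 3e6, height = 9, tau = 5e4))
  ss <- simulate_gwas(20000, c("1" = 8e6, "2" = 6e6), peaks = planted,
                      seed = 99)
  pk <- quickpeak(ss, p_cutoff = 1e-6, span = 1e6)
  expect_equal(nrow(pk), 3)
  # each peak within 2*tau of its causal position
  for (k in seq_len(3)) {
    d <- abs(pk$pos[pk$chrom == planted$chrom[k]] - planted$causal_pos[k])
    expect_true(any(d <= 2 * 5e4))
  }
  expect_true(oracle_check_exclusion(pk, 1e6))
  # identical to the exhaustive oracle
  orc <- oracle_quickpeak(as.data.frame(ss), 1e-6, 1e6)
  expect_equal(pk$pos, orc$pos)
  expect_equal(pk$p, orc$p)
})

test_that("quickpeak equals the brute-force oracle on varied random inputs", {
  for (seed in 1:20) {
    ss <- random_stats(800, seed = seed)
    cutoff <- sample(c(1e-2, 1e-3, 1e-4), 1)
    span <- sample(c(5e4, 2e5, 1e6), 1)
    pk <- quickpeak(ss, p_cutoff = cutoff, span = span)
    orc <- oracle_quickpeak(as.data.frame(ss), cutoff, span)
    expect_equal(peak_records(pk), peak_records(orc),
                 info = paste("seed", seed))
  }
})

test_that("max_peaks truncates in rank order and equals the oracle", {
  ss <- random_stats(1000, seed = 33)
  pk_all <- quickpeak(ss, p_cutoff = 1e-2, span = 1e5)
  pk_3 <- quickpeak(ss, p_cutoff = 1e-2, span = 1e5, max_peaks = 3)
  expect_equal(peak_records(pk_3), peak_records(pk_all[1:3, ]))
})

test_that("lowering the cutoff never adds peaks; the rank-1 peak survives any span", {
  ss <- random_stats(1500, seed = 8)
  spans <- c(1e4, 1e5, 1e6)
  cutoffs <- c(1e-2, 1e-3, 1e-4, 1e-5)
  top <- quickpeak(ss, p_cutoff = 1e-2, span = 1e5)[1, ]
  prev <- Inf
  for (ct in cutoffs) {
    n <- nrow(quickpeak(ss, p_cutoff = ct, span = 1e5))
    expect_lte(n, prev)
    prev <- n
  }
  for (sp in spans) {
    pk <- quickpeak(ss, p_cutoff = 1e-2, span = sp)
    expect_equal(pk$pos[1], top$pos)
  }
})

test_that("quickpeak is deterministic across runs and under p-value ties", {
  ss <- as_sumstats(data.frame(
    chrom = c("2", "1", "1"), pos = c(10, 900, 100),
    p = rep(1e-9, 3), id = c("rc", "rb", "ra")))
  pk1 <- quickpeak(ss, p_cutoff = 1e-6, span = 100)
  pk2 <- quickpeak(ss, p_cutoff = 1e-6, span = 100)
  expect_identical(as.data.frame(pk1), as.data.frame(pk2))
  # tie rule: chromosome rank, then position
  expect_equal(pk1$id, c("ra", "rb", "rc"))
})

test_that("runtime grows near-linearly with record count", {
  # trend assertion only: 8x the records should cost far less than ~24x
  t_small <- system.time(quickpeak(random_stats(20000, seed = 1),
                                   p_cutoff = 1e-3))[["elapsed"]]
  t_big <- system.time(quickpeak(random_stats(160000, seed = 2),
                                 p_cutoff = 1e-3))[["elapsed"]]
  expect_lt(t_big, max(24 * max(t_small, 0.02), 2))
})

test_that("peaks_to_loci centres fixed-width windows and clips at pos 1", {
  ss <- as_sumstats(data.frame(chrom = "1", pos = c(5e6, 2e5),
                               p = c(1e-10, 1e-9), id = c("rs1", "rs2")))
  pk <- quickpeak(ss, p_cutoff = 1e-6, span = 1e6)
  loci <- peaks_to_loci(pk, ss, window_width = 1e6)
  centred <- loci[[which(vapply(loci, function(l) l$index$id == "rs1",
                                logical(1)))]]
  expect_equal(centred$start, 4500001)
  expect_equal(centred$end, 5500000)
  clipped <- loci[[which(vapply(loci, function(l) l$index$id == "rs2",
                                logical(1)))]]
  expect_equal(clipped$start, 1)
  expect_equal(clipped$end - clipped$start + 1, 1e6)  # width preserved
})

test_that("each expanded locus contains its own peak as index variant", {
  planted <- dplyr::bind_rows(
    peak_spec("1", 2e6, height = 10), peak_spec("1", 5e6, height = 9),
    peak_spec("2", 3e6, height = 10))
  ss <- simulate_gwas(15000, c("1" = 7e6, "2" = 6e6), peaks = planted,
                      seed = 5)
  pk <- quickpeak(ss, p_cutoff = 1e-6, span = 1e6)
  loci <- peaks_to_loci(pk, ss, window_width = 1e6)
  expect_length(loci, nrow(pk))
  for (i in seq_along(loci)) {
    expect_equal(loci[[i]]$index$id, pk$id[i])
    expect_true(pk$pos[i] >= loci[[i]]$start && pk$pos[i] <= loci[[i]]$end)
  }
})

test_that("peak TSV and BED exports use the documented conventions", {
  ss <- tiny_stats()
  pk <- quickpeak(ss, p_cutoff = 1e-6, span = 100)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(pk, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(names(back), c("chrom", "pos", "id", "p", "rank"))
  bed <- withr::local_tempfile(fileext = ".bed")
  peaks_to_bed(pk, bed)
  bed_df <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  # 0-based half-open: start = (pos - span/2) - 1, clipped at 0
  expect_equal(bed_df$X2, pmax(0, pk$pos - 50 - 1))
  expect_equal(bed_df$X3, pk$pos + 50)
})
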
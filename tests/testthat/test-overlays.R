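# Overlays: LD binning, recombination tracks (bedGraph coordinates,
# last-wins overlap resolution, point queries), eQTL tables, and additive
# attachment to a locus.

test_that("ld_category bins with left-closed boundaries and special levels", {
  expect_equal(as.character(ld_category(0.85)), "0.8-1.0")
  expect_equal(as.character(ld_category(0.2)), "0.2-0.4")  # left-closed
  expect_equal(as.character(ld_category(1.0)), "0.8-1.0")  # top bin closed
  expect_equal(as.character(ld_category(0)), "0.0-0.2")
  expect_equal(as.character(ld_category(NA)), "none")
  expect_equal(as.character(ld_category(0.5, index = TRUE)), "index")
  expect_error(ld_category(1.5), class = "locusviz_domain_error")
  expect_error(ld_category(-0.1), class = "locusviz_domain_error")
  expect_true(is.ordered(ld_category(0.3)))
})

test_that("ld_category is a total order-preserving map on [0,1] + NA", {
  r2 <- withr::with_seed(21, c(stats::runif(500), NA, 0, 1))
  cat <- ld_category(r2)
  expect_false(any(is.na(cat)))
  ok <- !is.na(r2)
  expect_true(all(diff(as.integer(cat[ok][order(r2[ok])])) >= 0))
})

test_that("binned counts match the brute-force histogram", {
  r2 <- withr::with_seed(22, stats::runif(2000))
  counts <- table(ld_category(r2))
  orc <- oracle_ld_histogram(r2)
  for (nm in names(orc)) {
    expect_equal(unname(counts[nm]), unname(as.table(orc)[nm]), info = nm)
  }
})

test_that("load_ld validates rows and adds the implicit index self-r2", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tr2", "rs1\t0.9", "rs2\t0.1", "rs3\t1.5"), f)
  expect_warning(ld <- load_ld(f, index_id = "rs_idx"), "outside")
  expect_equal(nrow(ld), 3)  # rs3 dropped, rs_idx added
  expect_equal(ld$r2[ld$id == "rs_idx"], 1)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "x\t1"), bad)
  expect_error(load_ld(bad), class = "locusviz_config_error")
})

test_that("bedGraph coordinates convert to 1-based inclusive on read", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t10.5", "chr1\t100\t250\t3.25"), f)
  tr <- load_recomb(f)
  expect_equal(tr$chrom, c("1", "1"))
  expect_equal(tr$start, c(1, 101))
  expect_equal(tr$end, c(100, 250))
  expect_equal(tr$rate, c(10.5, 3.25))
  # abutting intervals are kept, not merged
  expect_equal(nrow(tr), 2)
})

test_that("overlapping source intervals resolve last-wins with a warning", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("1\t0\t100\t5", "1\t50\t150\t7"), f)
  expect_warning(tr <- load_recomb(f), "last-wins")
  expect_equal(recomb_rate_at(tr, "1", 30), 5)
  expect_equal(recomb_rate_at(tr, "1", 60), 7)
  expect_equal(recomb_rate_at(tr, "1", 120), 7)
  # coverage is still contiguous over [1, 150]
  expect_equal(sum(tr$end - tr$start + 1), 150)
})

test_that("a constant-rate track returns that constant at any position", {
  tr <- simulate_recomb("1", 1e5, 1, seed = 1)
  tr$rate <- 2.5
  pos <- withr::with_seed(2, sample.int(1e5, 50))
  expect_equal(recomb_rate_at(tr, "1", pos), rep(2.5, 50))
  expect_true(is.na(recomb_rate_at(tr, "1", 1e5 + 1)))
  expect_true(all(is.na(recomb_rate_at(tr, "2", pos))))
})

test_that("recomb tracks round-trip through bedGraph write/read", {
  tr <- simulate_recomb("7", 5e5, 20, seed = 3)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- load_recomb(f)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$rate, tr$rate, tolerance = 1e-6)
  expect_equal(sum(back$end - back$start + 1), 5e5)  # contiguous cover
})

test_that("attach_overlays joins LD by id and leaves uncovered variants NA", {
  loc <- locus(tiny_stats(), chrom = "7", start = 1, end = 1000)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tr2", "rs1\t0.9", "rs2\t1.0"), f)
  loc <- attach_overlays(loc, ld = load_ld(f))
  td <- tidy(loc)
  expect_equal(as.character(td$ld_cat[td$id == "rs3"]), "none")
  expect_equal(as.character(td$ld_cat[td$id == "rs1"]), "0.8-1.0")
  expect_equal(as.character(td$ld_cat[td$id == "rs2"]), "index")
})

test_that("attachment is additive: variant records never change", {
  loc <- demo_locus(seed = 12, with_overlays = FALSE)
  before <- loc$data[, c("chrom", "pos", "p", "id")]
  loc2 <- attach_overlays(
    loc,
    ld = simulate_ld(loc, tau = 5e4, seed = 1),
    recomb = simulate_recomb("1", 5e6, 40, seed = 2),
    eqtl = simulate_eqtl(loc, seed = 3))
  expect_identical(loc2$data[, c("chrom", "pos", "p", "id")], before)
})

test_that("recomb attachment clips to the window and errors on chromosome mismatch", {
  loc <- demo_locus(seed = 13, with_overlays = FALSE)
  tr <- simulate_recomb("1", 5e6, 60, seed = 4)
  loc2 <- attach_overlays(loc, recomb = tr)
  expect_true(all(loc2$recomb$start >= loc$start))
  expect_true(all(loc2$recomb$end <= loc$end))
  wrong <- simulate_recomb("9", 5e6, 10, seed = 5)
  expect_error(attach_overlays(loc, recomb = wrong),
               class = "locusviz_join_error")
})

test_that("attached recomb samples equal brute-force point queries", {
  for (seed in 1:5) {
    tr <- simulate_recomb("1", 5e6, 100, seed = seed)
    loc <- demo_locus(seed = seed + 20, with_overlays = FALSE)
    loc <- attach_overlays(loc, recomb = tr)
    pos <- withr::with_seed(seed, sample(seq(loc$start, loc$end), 100))
    expect_equal(recomb_rate_at(loc$recomb, "1", pos),
                 recomb_rate_at(tr, "1", pos))
  }
})

test_that("recomb resampling conserves the track integral over the window", {
  for (seed in 1:10) {
    tr <- simulate_recomb("1", 5e6, sample(5:150, 1), seed = seed)
    loc <- suppressWarnings(
      locus(random_stats(50, seed), chrom = "1", start = 1.2e6, end = 3.4e6))
    loc <- attach_overlays(loc, recomb = tr)
    got <- sum((loc$recomb$end - loc$recomb$start + 1) * loc$recomb$rate)
    want <- oracle_track_integral(tr, "1", 1.2e6, 3.4e6)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("eQTL tables load, validate, and filter to the locus window", {
  loc <- demo_locus(seed = 30, with_overlays = FALSE)
  eq <- simulate_eqtl(loc, gene = "GENE2", tissue = "liver", seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eqtl(eq, f)
  back <- load_eqtl(f)
  expect_equal(nrow(back), nrow(eq))
  expect_true(all(back$direction %in% c(-1, 0, 1)))
  loc2 <- attach_overlays(loc, eqtl = back)
  expect_true(all(loc2$eqtl$pos >= loc$start & loc2$eqtl$pos <= loc$end))
})

test_that("simulated LD decays with distance and stays in [0, 1]", {
  loc <- demo_locus(seed = 40, with_overlays = FALSE)
  ld <- simulate_ld(loc, tau = 5e4, seed = 7)
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1))
  expect_equal(ld$r2[ld$id == loc$index$id], 1)
  d <- abs(loc$data$pos[match(ld$id, loc$data$id)] - loc$index$pos)
  expect_lt(stats::cor(d, ld$r2, method = "spearman"), -0.5)
})
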
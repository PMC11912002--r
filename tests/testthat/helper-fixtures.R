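# Programmatic fixtures shared across test files. All randomness is seeded
# by the caller; nothing is read from disk that a test did not just write.

tiny_stats <- function() {
  as_sumstats(data.frame(
    chrom = c("7", "7", "7"),
    pos = c(50, 150, 250),
    p = c(0.5, 1e-8, 0.2),
    id = c("rs1", "rs2", "rs3")
  ))
}

# random summary statistics for oracle comparisons: a few chromosomes,
# lumpy p-value distribution so some records fall below tight cutoffs
random_stats <- function(n, seed) {
  withr::with_seed(seed, {
    chrom <- sample(c("1", "2", "X"), n, replace = TRUE)
    pos <- sample.int(5e6, n, replace = TRUE)
    p <- 10^(-stats::rexp(n, rate = 1 / 2.5))
    as_sumstats(data.frame(chrom = chrom, pos = pos, p = p,
                           id = sprintf("v%05d", seq_len(n))))
  })
}

random_gene_set <- function(n, seed, span_max = 1e6) {
  withr::with_seed(seed, {
    start <- sample.int(span_max, n, replace = TRUE)
    width <- sample.int(round(span_max / 5), n, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("G%03d", seq_len(n)),
      symbol = sprintf("GENE%d", seq_len(n)),
      chrom = "1",
      start = start,
      end = start + width,
      strand = sample(c("+", "-"), n, replace = TRUE),
      biotype = "protein_coding",
      exons = lapply(seq_len(n), function(i) {
        tibble::tibble(start = start[i], end = start[i] + width[i])
      })
    )
  })
}

# hand-written GFF3/GTF pair encoding the same two-exon gene
fixture_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "7\ttest\tgene\t1000\t5000\t.\t+\t.\tID=gene:G1;Name=ABC1;biotype=protein_coding",
    "7\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=tx:T1;Parent=gene:G1",
    "7\ttest\texon\t1000\t1500\t.\t+\t.\tParent=tx:T1",
    "7\ttest\texon\t4000\t5000\t.\t+\t.\tParent=tx:T1"
  ), path)
  path
}

fixture_gtf <- function(path) {
  writeLines(c(
    paste0("7\ttest\tgene\t1000\t5000\t.\t+\t.\t",
           'gene_id "G1"; gene_name "ABC1"; gene_biotype "protein_coding";'),
    paste0("7\ttest\ttranscript\t1000\t5000\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("7\ttest\texon\t1000\t1500\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("7\ttest\texon\t4000\t5000\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";')
  ), path)
  path
}

# a ready-made locus with all overlays attached, for plotting tests
demo_locus <- function(seed = 7, with_overlays = TRUE) {
  ss <- simulate_gwas(3000, c("1" = 5e6),
                      peaks = peak_spec("1", 2.5e6, height = 10,
                                        tau = 5e4),
                      seed = seed)
  ann <- simulate_genes("1", c(2e6, 3e6), n_genes = 6, seed = seed + 1)
  loc <- locus(ss, chrom = "1", start = 2e6, end = 3e6, annotation = ann)
  if (with_overlays) {
    loc <- attach_overlays(
      loc,
      ld = simulate_ld(loc, tau = 5e4, seed = seed + 2),
      recomb = simulate_recomb("1", 5e6, 80, seed = seed + 3),
      eqtl = simulate_eqtl(loc, gene = "GENE1", seed = seed + 4)
    )
  }
  loc
}
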
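# locusviz

Publication-ready regional association ("locus zoom") plots and a very fast
peak scanner for GWAS summary statistics, in R.

## Who this is for

Statistical geneticists and genetic epidemiologists who have a genome-wide
summary-statistics file (chromosome, position, p-value, …) and need, for a
paper or a report:

* a figure for one locus: a −log₁₀(p) scatter panel aligned *exactly* over a
  gene-exon track, coloured by linkage disequilibrium (LD) r² against the
  index variant, with the local recombination rate on a secondary axis and,
  optionally, a stacked eQTL panel for a candidate gene;
* or all of the above for **every** independent significant locus in the
  scan, exported as one multi-page PDF.

All tabular inputs and outputs are tibbles; locus objects have `tidy()` /
`glance()` methods and plot with `autoplot()`, so the package composes with
the usual tidyverse workflow.

## The core methods

**Peak scanning.** `quickpeak()` implements greedy select-and-exclude over
the records with p below a cutoff: the smallest remaining p becomes the next
peak and masks everything on its chromosome within span/2 of it, so any two
reported peaks on one chromosome are more than span/2 apart. Defaults are
the conventional genome-wide threshold p < 5 × 10⁻⁸ and a 1 Mb span (equal
to the default plotting window, so one parameter governs both the peak list
and the figures). The implementation is a single sort plus interval masking
— near-linear in the number of records — and is contractually identical to
a brute-force re-scan, which the test suite verifies on hundreds of random
inputs.

**Gene-track layout.** `layout_gene_track()` packs gene models into
non-overlapping display rows by greedy first-fit over each gene's extent
(window-clipped span plus label box). With zero-width labels this is the
optimal interval-graph colouring: rows used = maximum overlap depth.

**Coordinate discipline.** Everything internal is 1-based inclusive;
bedGraph/BED (0-based half-open) are converted at the reader/writer
boundary; chromosome labels are normalised across UCSC/Ensembl styles.
`assemble_figure()` refuses to stack panels whose windows differ and pins
every panel to bit-identical x-limits.

**Overlays and caching.** LD tables, recombination tracks (bedGraph/bigWig)
and eQTL tables attach additively to a locus from local files; remote
services plug in behind a provider contract with a persistent on-disk cache
(`cached_fetch()`), so repeated queries — even across R sessions — fetch
once.

**Synthetic data.** `simulate_gwas()` (uniform background p-values plus
planted exponentially-decaying association peaks), `simulate_genes()`,
`simulate_ld()`, `simulate_recomb()` and `simulate_eqtl()` generate
everything the package consumes, deterministically from a seed, so the
whole pipeline runs and tests with no downloads.

## A worked example

```r
library(locusviz)

ss <- simulate_gwas(10000, c("1" = 1e7),
                    peaks = peak_spec("1", causal_pos = 5e6,
                                      height = 10, tau = 5e4),
                    seed = 42)
ss
#> # GWAS summary statistics: 10,000 variants on 1 chromosome(s)
#> # A tibble: 10,000 × 6
#>   chrom   pos id              p direction typed
#> 1 1       264 snp_000001 0.0525         1 FALSE
#> 2 1       494 snp_000002 0.155          1 TRUE
#> ...

quickpeak(ss, p_cutoff = 5e-8, span = 1e6)
#> # A tibble: 1 × 7
#>    rank chrom     pos id                p window_start window_end
#> 1     1 1     5002185 snp_005004 1.10e-10      4502185    5502185
```

One peak: the most significant variant (`snp_005004`, p = 1.1 × 10⁻¹⁰) sits
2.2 kb from the planted causal position at 5 Mb, and its 1 Mb exclusion
window suppresses the surrounding shoulder of the same signal. Build and
draw the locus:

```r
ann <- simulate_genes("1", c(4.5e6, 5.5e6), n_genes = 8, seed = 1)
loc <- locus(ss, chrom = "1", start = 4500001, end = 5500000,
             annotation = ann)
loc <- attach_overlays(loc,
                       ld = simulate_ld(loc, tau = 5e4, seed = 2),
                       recomb = simulate_recomb("1", 1e7, 200, seed = 3))
loc
#> # locus 1:4,500,001-5,500,000
#> #   1018 variant(s), 8 gene(s); index snp_005004 (p = 1.1e-10)
#> #   overlays: ld, recomb

fig <- plot_locus(loc, labels = TRUE, highlight = "GENE3")
export_figure(fig, "locus.pdf")      # also .svg / .png
export_html(fig, "locus.html")       # self-contained, hover to identify points
```

The figure stacks the LD-coloured scatter (index variant as a purple
diamond, labelled, recombination rate as a step line on the right axis)
over the gene track, with `GENE3` highlighted in red and every panel
sharing the same x-limits exactly.

### Command line

The installed `locusplot` script wraps the same functions:

```sh
locusplot peaks --stats gwas.tsv --p-cutoff 5e-8 --span 1000000 --out peaks.tsv
locusplot plot  --stats gwas.tsv --genes genes.gff3 \
                --region 1:4500001-5500000 --recomb recomb.bedgraph \
                --highlight GENE3 --out locus.pdf
locusplot batch --config run.yaml --out all_loci.pdf   # one page per peak
```

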
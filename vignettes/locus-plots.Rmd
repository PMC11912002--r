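---
title: "Regional locus plots and fast peak scanning with locusviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional locus plots and fast peak scanning with locusviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 6)
library(locusviz)
```

## The problem

A regional association ("locus zoom") plot shows per-variant GWAS evidence,
$-\log_{10}(p)$ against genomic position, directly above the gene-exon models
of the same window, usually decorated with linkage disequilibrium (LD) around
the most significant variant, the local recombination-rate profile, and often
a second panel of eQTL evidence for a candidate gene. The figure is only
trustworthy if every panel shares *exactly* the same x-coordinates: a
scatter panel whose axis expansion differs from the gene track's by even a
few kilobases silently misplaces variants relative to exons. locusviz is
built around that guarantee — panels carry their window as metadata,
`assemble_figure()` refuses to stack panels whose windows differ, and all
panels are pinned to identical limits with no axis expansion.

The second half of the package is scale: a genome-wide scan routinely holds
millions of variant records, and a paper figure set needs every independent
significant locus, not one hand-picked region. `quickpeak()` extracts all
independent peaks from a summary-statistics table in a single pass, and the
batch workflow turns each peak into a fixed-width locus figure streamed to a
multi-page PDF.

## The model and its conventions

**Coordinates.** Everything internal is 1-based inclusive, the GFF/GTF and
GWAS convention. BED-family inputs (bedGraph, bigWig) are 0-based half-open
and converted once at the reader boundary; BED output converts back on
write. A single internal frame prevents off-by-one drift between panels.

**Chromosome labels.** `chr7`/`7`, `chrX`/`X`, `M`/`MT` are normalised to
the Ensembl-style bare label before any comparison, so mixed UCSC/Ensembl
inputs join correctly.

**The display transform.** `neglog10()` maps p to $-\log_{10}(p)$.
Underflowed `p = 0` values, common in very large meta-analyses, are capped
at a configurable ceiling (default 300, about the double-precision limit)
with a warning, keeping axes finite without discarding the record.

**The peak scanner.** `quickpeak()` implements greedy select-and-exclude:
take the unmasked record with the smallest p below `p_cutoff`, emit it as
the next peak, mask every record on the same chromosome within `span/2` of
it, repeat. Two accepted peaks on one chromosome are therefore always more
than `span/2` apart. The defaults are `p_cutoff = 5e-8` (the conventional
genome-wide significance level) and `span = 1e6`; the exclusion span
deliberately equals the default 1 Mb plotting window so the peak list and
the batch figures are governed by one parameter. Ties in p are broken by
chromosome rank, then position, then lexicographic variant id — an
arbitrary but fixed rule chosen so that output is reproducible; this
matters in practice because capped p-values tie exactly. The implementation
is one sort of the below-cutoff candidates plus a nearest-accepted-distance
check, so cost is dominated by the sort and grows near-linearly in the
record count; its contract is defined by equality with a brute-force
re-scan oracle, which the test suite enforces on hundreds of random
instances. Peaks are distance-pruned only: the scanner is not LD-aware
clumping and performs no conditional analysis.

**Gene-track layout.** `layout_gene_track()` packs genes into display rows
by greedy first-fit over extents, where a gene's extent is its
window-clipped span widened by its label box. Labels sit to the left of the
span and flip to the right when the left edge would leave the window; label
width is estimated as character count times a per-character genomic width
(default 0.9 % of the window per character — about what an italic
gene-symbol glyph occupies in a typical single-column figure). With zero
label widths, first-fit ordered by interval start is optimal for interval
graphs, so the number of rows equals the maximum overlap depth; the test
suite checks this against an independent sweep-line oracle. A `max_rows`
cap moves overflow genes into a `clipped` set reported as a "+N more"
caption rather than growing the track without bound. Transcript detail is
deliberately collapsed to one model per gene (the union of exons across
transcripts): regional plots read best with one row per gene, and
per-transcript drawing is out of scope.

**LD binning.** `ld_category()` uses the classic five 0.2-wide r² bins,
left-closed with the top bin `[0.8, 1.0]` closed, plus a grey `none`
category for variants without LD data and a distinct `index` category.
Colours (red descending to navy, purple index) are the long-standing
convention for these figures and fully overridable via `ld_colors()` /
the `colors` argument.

**Recombination overlay.** Tracks are piecewise-constant (bedGraph
semantics). Attachment clips intervals to the locus window, which exactly
conserves the rate-times-length integral — checked against a brute-force
source-interval integral at tolerance 1e-9 in the tests. The overlay draws
as a step line against a fixed 0-100 cM/Mb right-hand axis by default
(configurable), so figures from different loci remain visually comparable.
Overlapping source intervals are resolved last-wins with a warning;
abutting intervals are kept, never merged.

**Label placement.** `place_labels()` nudges label boxes vertically,
processing points from the top down, until no two boxes intersect; a leader
line connects each box to its point. Greedy nudging is not globally optimal
but is deterministic, fast, and guarantees disjoint boxes, which is the
property the tests assert.

**Providers and caching.** LD, recombination and eQTL data commonly come
from slow rate-limited web APIs. Every provider is a `fetch(key)` function
wrapped by a persistent on-disk cache (`cached_fetch()`): one underlying
fetch per unique key, including across R sessions pointed at the same cache
directory. The package ships file-backed providers (the recommended setup
for batch runs over many loci); live network clients plug into the same
contract and are intentionally not exercised by the test suite. Any API
token such a client needs should be read from the environment and never
logged.

## What the synthetic generator emulates — and what it does not

All tests and the acceptance script run on data from the `simulate_*`
family, which are pure functions of their parameters and a seed.

`simulate_gwas()` draws variant positions uniformly over chromosomes
(chromosome chosen proportional to length) and background p-values from
Uniform(0, 1) — equivalently, background $-\log_{10}(p)$ is Exponential
with mean $\log_{10}(e) \approx 0.4343$. A planted association at
`causal_pos` contributes a decaying envelope
$h\,e^{-d/\tau} + \mathcal{N}(0, 0.25^2)$ on the $-\log_{10}$ scale for
variants within $5\tau$ of the causal position (the Gaussian jitter is
read as a standard deviation of 0.25), combined with the background by
taking the maximum and flooring at zero. Default peak parameters used
throughout the tests are height 8-12 and $\tau$ = 50 kb, which produce
peaks of realistic width and strength for a well-powered GWAS locus at the
default 1 Mb window.

This model creates realistic-*looking* loci but deliberately does not model
LD-driven correlation between neighbouring p-values, allele frequencies, or
coalescent structure. Consequently, passing tests demonstrate the
correctness of the scanning, windowing, layout and rendering machinery —
not robustness to the correlated significance plateaus real LD produces.
Because the scanner is distance-pruned, correlated neighbours are masked by
the exclusion span in exactly the same way whether or not their p-values
are correlated, so this simplification does not change the greedy
semantics being tested.

`simulate_genes()`, `simulate_recomb()`, `simulate_ld()` and
`simulate_eqtl()` follow the same philosophy: structurally valid output
(exons inside spans, contiguous track coverage, r² in [0, 1] decaying with
distance at rate $\tau$) that round-trips exactly through the package's
writers and readers (GFF3, bedGraph, TSV).

## Numerical and degenerate-input choices

* Malformed summary-statistics rows (missing chromosome/position,
  unparseable positions, p outside [0, 1]) are dropped with a reported
  count rather than aborting: multi-million-row downloads almost always
  contain a few artefact rows, and a batch run should survive them.
* An empty locus window is a warning plus an empty locus, not an error;
  an empty peak scan is an empty table.
* Index-variant and peak ties: smallest p, then chromosome rank, position,
  id (see above).
* Loci centred near a chromosome start clip at position 1 while preserving
  the requested window width to the right.
* Figures are described per panel and assembled once; x-limits are set
  with `coord_cartesian(expand = FALSE)` so the limits of every panel in a
  figure are bit-identical, and SVG export of a fixed figure is
  byte-stable, which the suite uses for snapshot comparison.

## Problem sizes used by the tests and the acceptance script

The checked-in suite runs entirely on synthetic data at sizes chosen to
exercise every code path while keeping a full run around a minute: oracle
equivalence on 200 random tables of 200-10 000 records, parameter recovery
over 100 replicates of 10 000-variant genomes for 1, 3 and 5 planted peaks,
500 random gene sets for layout, 100 random recombination tracks, and a
three-peak batch PDF. `scripts/acceptance.R` recomputes the same quantities
from scratch with its own seed. The scanner itself has been designed (one
sort plus interval masking) so that the same code path handles
multi-million-row genome-wide files; loading is chunked so memory is
bounded by chunk size, not file size.

## Known limitations

* No allele/effect harmonisation and no genome-build liftover; inputs are
  taken in the coordinates they arrive in.
* Peak pruning is by distance only (no LD clumping or conditional
  analysis).
* One gene model per gene; no per-transcript isoform drawing.
* The interactive HTML export is a lightweight single-file SVG document
  with native hover tooltips — ideal for identifying points, but it does
  not offer zooming or linked brushing.
* Live LD/eQTL/recombination web services are supported only through the
  provider contract; the shipped providers are file-backed.

## A worked example

```{r example, eval = FALSE}
library(locusviz)

# a synthetic genome: 10 000 variants, one strong association on chr 1
ss <- simulate_gwas(
  n_snps = 10000, chrom_lengths = c("1" = 1e7),
  peaks = peak_spec("1", causal_pos = 5e6, height = 10, tau = 5e4),
  seed = 42)

# every independent peak at genome-wide scale
quickpeak(ss, p_cutoff = 5e-8, span = 1e6)

# a 1 Mb locus around the top signal, with gene models and overlays
ann <- simulate_genes("1", c(4.5e6, 5.5e6), n_genes = 8, seed = 1)
loc <- locus(ss, chrom = "1", start = 4500001, end = 5500000,
             annotation = ann)
loc <- attach_overlays(loc,
                       ld = simulate_ld(loc, tau = 5e4, seed = 2),
                       recomb = simulate_recomb("1", 1e7, 200, seed = 3),
                       eqtl = simulate_eqtl(loc, gene = "GENE3", seed = 4))

fig <- plot_locus(loc, labels = TRUE, highlight = "GENE3")
export_figure(fig, "locus.pdf")
export_html(fig, "locus.html")   # hover a point to identify it
```

The same workflow is available from a shell via the `locusplot` script
installed with the package (`peaks`, `plot` and `batch` subcommands); the
CLI is a thin wrapper over exactly these functions.
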
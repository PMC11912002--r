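Package: locusviz
Title: Regional Association Locus Plots and Fast Peak Scanning for GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Locusviz", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Publication-ready regional gene locus plots from genome-wide
    association study (GWAS) or other positional summary statistics:
    coordinate-exact -log10(p) scatter panels stacked over gene-exon tracks,
    with linkage-disequilibrium r-squared colour binning, recombination-rate
    overlays on a secondary axis, and stacked eQTL panels. Includes a very
    fast greedy peak scanner for extracting all independent significant loci
    from multi-million-row summary statistics, batch export of one figure per
    locus to a multi-page PDF, pluggable cached data providers, a synthetic
    data generator for self-contained testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    IRanges,
    jsonlite,
    optparse,
    patchwork,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
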
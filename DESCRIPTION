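Package: fragsites
Title: Fragile-Site Catalogues, Feature Enrichment and Histone-Signal
    Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with human common fragile site (CFS)
    catalogues: parsing cytogenetically and molecularly mapped site
    tables, merging them into disjoint genomic region sets, quantifying
    the density enrichment of cancer-pathway genes, miRNA precursors and
    CTCF binding sites inside fragile regions relative to the rest of
    the genome, and summarising histone-mark ChIP-seq signal per site as
    the difference between the site mean and its chromosome mean. A
    seedable synthetic-data generator emits genomes, fragile interval
    sets, feature catalogues with planted enrichment and signal tracks
    with planted per-region shifts so that every stage of the pipeline
    can be verified against known truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
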
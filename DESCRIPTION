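Package: triadNC
Title: Non-Coding RNA and Epigenome Integration for Parent-Hybrid Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integration layer for interspecific-hybridization studies that
    compare an allopolyploid maternal line, a diploid paternal line, and their
    F1 hybrid. Builds in-silico hybrids at a 1:1 parental ratio, classifies
    features into additive, expression-level-dominant and transgressive
    patterns, calls subgenome dosage-dependent features from ploidy-series
    correlations, classifies and filters long non-coding RNA and siRNA-cluster
    loci by genomic position, merges replicate accessible-chromatin peaks,
    computes weighted methylation levels, metaprofiles and 200-bp-bin
    differentially methylated regions, correlates ncRNAs with neighbouring and
    distant genes, and soft-clusters expression profiles. A synthetic-data
    generator with planted ground truth supports end-to-end recovery testing
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    limma,
    data.table,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
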
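Package: cinscope
Title: Single-Cell and Low-Pass Bulk Copy-Number Analysis of Chromosomal Instability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying chromosomal instability from binned
    read-count data. Simulates single-cell DLP-style and FFPE low-pass bulk
    whole-genome count matrices with known clonal structure, performs GC and
    mappability bias correction with blacklisting and cell-level quality
    filters, detects copy-number change points with an e-divisive energy
    statistic and calls integer states by ploidy-grid scaling, fits tumour
    cellularity and ploidy to relative bulk profiles by grid search over an
    error surface, computes population heterogeneity metrics (fraction of
    genome altered, Shannon entropy, per-bin CNA frequency), clusters cells
    into clades with a minimum-event copy-number distance and neighbor
    joining, and screens absolute profiles for focal amplifications and
    deletions overlapping cancer genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ape,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
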
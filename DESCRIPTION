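Package: haplosweep
Title: Haplotype-Based Selective Sweep Scans and Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of positive selection from phased two-population
    SNP data using extended haplotype homozygosity statistics (iHS and XP-EHH),
    windowed pooled heterozygosity (Hp and its genome-wide Z-transform ZHp),
    and windowed nucleotide diversity, then intersects the significant sweep
    gene sets with differentially expressed genes to produce a per-gene report.
    Includes a deterministic two-population hard-sweep simulator (founder-copy
    mosaic haplotypes with an imposed sweep haplotype) so the whole pipeline can
    be exercised and validated without external data, plus a thin command-line
    driver with run manifests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
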
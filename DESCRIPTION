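Package: adaptscan
Title: Selective-Sweep Scans, Environmental Association and Adaptive-Trait
    Analytics for Structured Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying local adaptation in
    structured diploid populations such as crop landrace panels.  Provides a
    forward-time Wright-Fisher simulator with migration and hard selective
    sweeps for generating benchmark data with known ground truth; windowed
    diversity and differentiation scans (nucleotide diversity, Tajima's D,
    Weir-Cockerham FST, reduction of diversity); sweep-model scans (composite
    likelihood ratio against the genome-wide site-frequency spectrum, a
    mu-type composite of SNP density, SFS shape and linkage disequilibrium,
    and the integrated haplotype score); a consensus caller that merges
    top-quantile outlier windows supported by two or more metrics into
    candidate selection regions; genome-wide environmental association via an
    EMMAX-style mixed model and a latent-factor ridge model with genomic
    control; and adaptive-trait analytics (AMMI genotype-by-year
    decomposition of multiyear bloom dates, bloom-date-advance regression,
    logistic LT50 cold-hardiness fitting, chilling-hour accumulation, and
    multiyear association stability classes).  Cross-stage synthesis covers
    gene-level overlap of sweeps with association signals and Mantel tests of
    genetic versus environmental distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
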
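Package: methTier
Title: Data-Driven Tiering of Differential DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and tiers differential DNA methylation between two
    groups of samples from a normalized beta-value matrix (e.g. Illumina
    450K). Per-CpG shifts are estimated with the Hodges-Lehmann statistic,
    the genome-wide shift distribution is modelled as a univariate Gaussian
    mixture fitted by EM with BIC model selection, and maximum-probability
    (MAP) intersection points of the weighted component densities provide
    data-driven cutoffs that grade significant sites into medium, high and
    extreme-high tiers. Site-level evidence from one-sided rank tests is
    corrected by Storey's q-values and integrated to gene TSS/Body regions
    and arbitrary genomic features (lincRNAs, enhancers, transposable
    elements) with Stouffer's method. Includes a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
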
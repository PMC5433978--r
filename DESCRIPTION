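Package: FstScan
Title: Windowed FST Outlier Scans with Density-Matched Bootstrap Nulls
    and Statistical-Parsimony Haplotype Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting candidate loci under divergent selection
    between two closely related populations from exonic SNP data. Implements
    the two-population Weir-Cockerham FST estimator with full variance
    components, per-site nucleotide diversity, sliding-window summaries,
    Tajima's D in nonoverlapping windows, a SNP-density-matched bootstrap
    null distribution for window significance, top-percentile SNP ranking
    with per-gene outlier counts, length- and density-matched scaffold
    selection for comparable visualisation, and statistical-parsimony
    (TCS-style) haplotype network construction. Includes a Balding-Nichols
    synthetic-data generator with planted outlier clusters so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Software
RoxygenNote: 7.3.3
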
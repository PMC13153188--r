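Package: ephub
Title: Enhancer-Promoter Regulatory Hub Networks from Chromatin and
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the computational building blocks
    used to nominate tumor-specific long non-coding RNAs and to map their
    downstream enhancer-promoter regulatory hubs: a six-step candidate
    lncRNA filter cascade with positional classification, ROSE-style
    super-enhancer stitching and rank-curve calling, construction of a
    weighted gene-peak regulatory network with head-node augmentation and
    weighted eigenvector centrality hub scoring, a network activity score
    with maximally-selected-rank-statistic survival stratification, and
    aggregate peak analysis (APA) of HiChIP contact matrices. A synthetic
    data module generates every input with planted ground truth so the
    whole pipeline is testable without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
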
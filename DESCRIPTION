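Package: eDNAtank
Title: In Silico Primer Evaluation and Tank Metabarcoding Simulation for
    Freshwater Fish eDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating fish environmental DNA (eDNA)
    metabarcoding primer pairs and for benchmarking the downstream
    quantification workflow in silico. Provides an IUPAC-aware ungapped
    in silico PCR engine for degenerate primers, per-primer screening
    statistics (taxonomic coverage, barcode length, taxonomic
    resolution, amplification-success curves), a seeded mock-community
    ("tank") read simulator with biomass-proportional eDNA shedding and
    primer-specific amplification efficiencies, an amplicon read
    pipeline (pair merging, quality filtering, primer trimming, greedy
    97% OTU clustering, taxonomic assignment, rarefaction, accumulation
    curves), and the statistical layer relating read counts to species
    biomass through linear mixed-effects models and permutation t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
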
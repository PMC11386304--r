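Package: rohdiv
Title: Runs of Homozygosity, Inbreeding and Genetic Diversity from
    Whole-Genome SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inbreeding and diversity analysis of small
    whole-genome resequencing panels of non-model species. Implements a
    VCF quality-filtering cascade with per-genotype depth/quality
    masking, a Hardy-Weinberg site filter based on the FIS*sqrt(N)
    statistic, per-individual heterozygosity and windowed nucleotide
    diversity with a missing-data-aware denominator over an "all sites"
    (polymorphic plus monomorphic) data set, sliding-window detection of
    runs of homozygosity (ROH) with support-based trimming, F_ROH with
    length-class decomposition and ROH-age mapping under a
    centimorgan-per-megabase calibration, and folded site-frequency
    spectrum construction with hypergeometric projection. Ships
    synthetic-data generators (Hardy-Weinberg/inbred genotype draws and
    a pedigree gene-dropping genome simulator with recombination and
    ground-truth autozygous tracts) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, VariantAnnotation, Genetics,
    Sequencing
RoxygenNote: 7.3.3
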
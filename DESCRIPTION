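Package: gbsCrossMap
Title: Genotyping-by-Sequencing Linkage Mapping and Binary-Trait QTL
    Analysis for Outcrossed F1 Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete pipeline for genetic mapping in heterozygous F1
    (double pseudo-testcross) populations genotyped by two-enzyme
    genotyping-by-sequencing (GBS). Provides barcode demultiplexing and
    read trimming for restriction-site-anchored libraries, construction
    and filtering of sparse genotype matrices from multi-sample VCF
    (depth masking, minor-allele-frequency and missingness thresholds),
    segregation analysis with Mendelian-inconsistency masking and
    chi-squared distortion tests, de novo linkage-map construction via
    two-point recombination-fraction estimation with linkage-phase
    inference, co-segregation binning, LOD-threshold grouping, seriation
    ordering and Kosambi distances, and binary-trait QTL mapping by both
    single-marker allelic association with Bonferroni control and
    interval mapping with permutation-derived genome-wide LOD thresholds.
    A built-in F1 GBS simulator (crossovers, phased parents, a planted
    binary QTL, negative-binomial read depth, read-level artefacts)
    supplies ground truth for every stage.
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
    VariantAnnotation,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, SNP, GeneticVariability, Sequencing, QualityControl
RoxygenNote: 7.3.3
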
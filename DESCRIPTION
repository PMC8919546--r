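Package: arrayvalid
Title: Analytical Validation of BeadChip Array Genotype Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for establishing the analytical validity of
    hybridization-array (BeadChip) genotype data by quality analytics and
    comparison to whole-genome-sequencing and benchmark truth sets. Provides
    per-sample and per-replicate quality control (call rate, p10GC,
    B-allele-frequency based contamination estimation, chip-position and
    replicate z-score outlier analysis, principal-component structure checks),
    genotype-pair classification and concordance / sensitivity / specificity /
    positive-predictive-value metrics, per-assay stratification by variant
    type, transition/transversion class, allele-frequency bin, low-complexity
    region and panel membership, a stepwise medically-actionable-panel filter,
    and a fully seeded synthetic-cohort simulator (Hardy-Weinberg truth
    genotypes, triplicate array call sets with per-stratum error, GenCall-like
    quality scores with a chip-row gradient, contamination as BAF mixing, and
    an independent WGS-like call set) so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
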
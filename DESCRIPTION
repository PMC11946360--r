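Package: ExomeScreen
Title: Targeted Screening of Phenotype-Associated Variants in Canine Whole-Exome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for using whole-exome sequencing as a screening instrument
    in veterinary clinical genetics. The package curates an OMIA-style
    catalogue of known phenotype-associated variants, qualifies every variant
    locus in every sample by per-base sequencing depth at fixed thresholds
    (10x/20x/30x), scans multi-sample VCF files for catalogue variants with
    allele normalization and inheritance-aware zygosity interpretation
    (autosomal, X-linked hemizygous, mitochondrial), summarises per-variant
    and per-sample performance, computes carrier-accumulation curves over
    random panel subsets, and assembles clinical-style screening reports with
    reportable-range and below-threshold-locus sections. A seed-deterministic
    synthetic-data generator emulates catalogues, depth tracks and VCFs with
    known ground truth so the whole pipeline is testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
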
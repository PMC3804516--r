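Package: panmut
Title: Pan-Genomic Mutation-Cohort Analysis for Adaptive Laboratory
    Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of resequenced mutation cohorts from adaptive
    laboratory evolution (ALE) experiments in bacteria.  Takes a
    per-sample variant table for a wild-type ancestor, serially sampled
    intermediate populations and endpoint single-colony isolates, and
    provides high-confidence variant screening, coding-effect
    classification, longitudinal mutation-accumulation profiles, the
    four-way pan-genome partition (core / shared / unique / discarded),
    rule-based mutational hotspot calling over genes, operons and
    pathways, PSSM-based function-change scoring of amino-acid
    substitutions, mutation-linked differential-expression analysis
    (upper-quartile normalisation, per-gene ANOVA with
    Benjamini-Hochberg FDR control and dual effect-size thresholds,
    hierarchical clustering), and growth-kinetics estimation with
    pairwise ANCOVA comparison.  A seeded synthetic-cohort generator
    emulates the full study design with planted ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
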
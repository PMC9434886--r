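Package: svscape
Title: Somatic Structural-Variant Landscape Analysis for Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale analysis of somatic structural variants (SVs)
    in cancer genomes: pairing of VCF breakends and simple-event classification,
    cross-caller concordance merging with a breakpoint-distance tolerance,
    per-tumour SV-type spectra and hyper-SV subtype calling, genome-binned
    breakpoint hotspot detection with Tukey fences and candidate driver-gene
    nomination, gene-fusion calling with fusion-mechanism and exon-junction
    classification, GISTIC-style gene copy-number state assignment, biallelic
    inactivation classification, and SV-burden versus mutation association
    testing. A synthetic cohort generator produces self-contained truth sets
    (two emulated caller views, gene annotation, copy-number and small-variant
    evidence) so that every stage can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
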
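Package: mirtekit
Title: Transposon-Derived miRNA Family Evolution and Sperm-Competition Analysis
Version: 0.1.0
Authors@R: person("mirtekit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale, fully synthetic-data-capable pipeline for studying
    the evolution of a transposon-derived, X-linked testis miRNA family.
    Provides seed-match target prediction over 3'UTRs (8mer/7mer-m8/7mer-A1/
    6mer site classes with optional G:U wobble), a lightweight differential-
    expression test with differentially-expressed-target (DET) selection and
    multi-knockout pooling, cross-species target-sharing and target-load
    statistics, per-base conservation mapping with target-site versus
    non-site contrasts, derived-allele-frequency and nucleotide-diversity
    comparisons, a transposon-origin screen (Smith-Waterman local alignment,
    base-pair-maximisation hairpin detection, directional substitution
    spectra), and goodness-of-fit statistics for sperm-competition assays.
    A synthetic-data module generates every input with known ground truth so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
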
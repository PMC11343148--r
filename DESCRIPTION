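Package: clipribo
Title: Abundance-Normalized CLIP Scores and RiboTag Integration for
    Cell-Type-Specific RNA-Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates cell-type-specific CLIP (crosslinking and
    immunoprecipitation) tag counts with RiboTag ribosome-association
    profiling. Computes transcript-abundance-normalized CLIP scores from a
    per-replicate linear regression of log2 CLIP TPM on log2 RiboTag TPM,
    classifies transcripts into stringent/high/low binding tiers, tests
    activity-induced differential binding with an empirical-Bayes moderated
    t-statistic, tests differential ribosome association with a simplified
    negative-binomial Wald model, and cross-classifies transcripts into a
    quadrant model of translational regulation. Ships a synthetic-data
    generator with known ground truth, genomic annotation of CLIP tags by
    biological complexity, and a small pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
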
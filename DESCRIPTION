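Package: residcog
Title: Multi-Omic Dissection of Residual Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multistep pipeline for identifying genes whose genetic,
    epigenetic, and transcriptomic variation converge on residual cognition,
    the part of late-life cognitive performance left unexplained by
    neuropathology and demographics. Provides the residual-cognition
    phenotype model, an additive genome-wide association scan with
    per-platform analysis and fixed-effect meta-analysis, greedy linkage
    disequilibrium clumping, a region-level DNA methylation omnibus test
    combining per-CpG p-values by Fisher's method against a permutation
    null, transcript-level association models, a sequential adjusted
    R-squared variance ledger, and a seeded synthetic multi-omic cohort
    generator with planted effects so that every stage can be validated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
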
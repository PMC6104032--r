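Package: introhap
Title: Haplotype-Based Analysis of Exotic Introgression in Topcross
    Pre-Breeding Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the genomic contribution of exotic (gene-bank) parents
    to inbred lines derived from exotic/elite1//elite2 three-way crosses and
    screens for rare, favorable exotic haplotypes. Provides marker quality
    control, confidence-interval D-prime haplotype-block construction with
    per-line haplotype classes, parent-of-origin (A/B/H) tracing against the
    three parents of each cross, mixed-linear-model association scans with
    kinship and BIC-selected principal-component covariates, and a
    rare-haplotype screen that excludes phenology-confounded blocks. A forward
    simulator of the topcross breeding scheme with per-segment ancestry truth
    makes every stage verifiable without the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
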
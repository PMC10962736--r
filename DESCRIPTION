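Package: mtisr
Title: Dependence Analysis of Mitochondrial Integrated Stress Response Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression in factorial stress-by-genotype designs
    (pooled-variance t tests, Benjamini-Hochberg FDR, fold-change/FDR DEG
    calling), classification of stress-responsive genes as modifier-dependent
    with a percent-dependence statistic based on knockout reversion of the
    stress effect, derivation of shared and k-of-n dependent-gene signatures
    across models with cross-tissue and cross-species (ortholog fold-change)
    overlaps, and rule-based morphometry of instance-segmentation label masks:
    equivalent-ellipse axes and aspect ratio, a nano-mitochondrion rule,
    myofiber cross-sectional area and per-fiber intensity quantification.
    A synthetic-data module plants factorial effect structure, dependence
    fractions, and ellipse/fiber geometry with machine-readable truth tables
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
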
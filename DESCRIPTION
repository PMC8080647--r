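Package: senquad
Title: Quadrant Enrichment of Nucleocytoplasmic Transport and mRNA Export
    Gene-Set Scores in Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-set signature scoring and two-dimensional quadrant
    enrichment analysis for cellular senescence transcriptomics. Provides a
    curated registry of mRNA export (TREX, TREX-2, TREX-associated factors)
    and classical nucleocytoplasmic transport (nuclear pore complex, nuclear
    transport receptors, Ran cycle) gene sets, per-study z-standardized
    mean-expression scores, median-split quadrant classification of samples,
    and exact one-sided Fisher enrichment tests with conditional
    maximum-likelihood odds ratios and exact one-sided confidence bounds.
    Includes deterministic cohort grouping rules (age dichotomies, age
    quartiles, tumor-stage dichotomies), a multi-study synthetic expression
    cohort simulator with latent-factor gene-gene correlation and batch
    effects for power and type-I-error studies, and a config-driven pipeline
    with TSV/GMT/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
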
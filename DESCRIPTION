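Package: matreoscreen
Title: Matrisome-Signature Drug Repurposing and Collagen-Reporter Dose
    Selection
Version: 0.1.0
Authors@R:
    person("Matreoscreen", "Developers", email = "matreoscreen@example.org",
           role = c("aut", "cre"))
Description: An extracellular-matrix-centred in-silico drug screening
    toolkit. Builds aged and youthful matreotype gene-expression signatures
    from age-stratified cohorts, scores drug perturbation z-score libraries
    for matrisome regulation (empirical size-matched null) and signature
    concordance, compiles directional hit lists with hypergeometric
    lifespan enrichment, mines compound literature tables for lifespan and
    ECM keyword evidence, and models a collagen promoter-driven GFP
    reporter assay for dose selection. A synthetic-data module generates
    every input with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
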
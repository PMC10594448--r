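Package: adcvault
Title: Antibody-Drug Conjugate Target Discovery with SPR Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A target-discovery pipeline for antibody-drug conjugate (ADC)
    development. Builds a queryable store of proteome annotation,
    transmembrane-topology predictions and immunohistochemistry (IHC)
    expression evidence; filters candidates by a single-pass transmembrane
    consensus and ranks them lexicographically on healthy-tissue and cancer
    expression keys; tests top-ranked genes for pathway overrepresentation
    (hypergeometric, BH-FDR); and analyses surface plasmon resonance (SPR)
    sensorgrams with double referencing, global 1:1 Langmuir kinetic fits,
    dissociation-only off-rate screening and the Chi-squared percent fit
    quality statistic. Ships seeded generators for every input so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
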
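Package: methsig
Title: Genome-Wide DNA Methylation Signatures of Glioblastoma Survival Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 450K-style DNA methylation array analysis
    contrasting long-term and short-term glioblastoma survivors: probe
    filtering and beta-value computation with detection p-values, BMIQ-style
    type-I/II intra-sample normalization, differential methylation by an
    inverse-method generalized-least-squares test using negative-control
    probes, CpG-island-context signature extraction, integration with histone
    marks, gene expression and somatic mutations, probe-bias-corrected gene
    ontology enrichment by weighted resampling, and a two-score survival-group
    classifier. Ships a seeded synthetic-cohort generator emulating the
    study's statistical structure so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
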
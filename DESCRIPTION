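Package: strainCR
Title: Strain-Resolved Transcriptome Analysis of Caloric Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analyzing transcriptional responses to caloric
    restriction (CR) across inbred mouse strains and tissues, and for
    comparing them with human adipose responses. Provides gene-level
    differential expression with empirical-Bayes moderated t-statistics,
    strain-by-diet interaction scans, likelihood-ratio factor-dominance
    summaries, principal-component CR response vectors, cross-strain
    shared-response counting against a permutation null,
    DerSimonian-Laird random-effects meta-analysis of paired human
    experiments, ortholog-mapped cross-species concordance scoring with
    a cumulative-overlap enrichment test, and a synthetic-data generator
    with planted ground truth that emulates the multi-strain CR study
    design at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor
Config/testthat/edition: 3
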